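cfg <- vestige_config()

## A mutant locus carrying a known 1-nt deletion, its annotation, and the
## matching wild-type haplotype (same locus with the deleted base restored).
deletion_world <- function(seed = 3) {
  m <- toy_model()
  tree <- toy_tree()
  cl <- evolve_clade(m, tree, 0.03, seed = seed)
  cl <- inject_lesion(cl, "A", list(type = "deletion", cds_coord = 60L,
                                    length = 1L))
  locus <- cl$loci[["A"]]
  aln <- locate_exons(m, locus, cfg)
  les <- call_lesions(aln, m, locus, cfg)
  lesion <- les[les$type == "deletion", ][1, ]
  wild <- paste0(substr(locus$seq, 1, lesion$locus_pos), lesion$ref_allele,
                 substr(locus$seq, lesion$locus_pos + 1, nchar(locus$seq)))
  list(model = m, locus = locus, lesion = lesion, wild = wild)
}

test_that("mutant-haplotype reads validate a lesion, wild-type reads do not", {
  w <- deletion_world()
  ctx <- list(seq = w$locus$seq, pos = w$lesion$locus_pos)
  mut_reads <- simulate_reads(w$locus$seq, depth = 8, read_len = 100,
                              seed = 5)$reads
  sup <- support_for_lesion(mut_reads, ctx, w$lesion, cfg)
  expect_gte(sup$n_support, cfg$min_supporting_reads)
  expect_identical(sup$n_contradict, 0L)
  expect_true(sup$validated)

  ## reads from the wild-type haplotype only contradict
  ref_reads <- simulate_reads(w$wild, depth = 8, read_len = 100,
                              seed = 6)$reads
  sup0 <- support_for_lesion(ref_reads, ctx, w$lesion, cfg)
  expect_identical(sup0$n_support, 0L)
  expect_gt(sup0$n_contradict, 0L)
  expect_false(sup0$validated)
})

test_that("a read ending inside the flank counts in neither bucket", {
  w <- deletion_world()
  p <- w$lesion$locus_pos
  ## read covering the lesion but with only 10 nt on the right side
  short <- substr(w$locus$seq, p - 60, p + 10)
  ctx <- list(seq = w$locus$seq, pos = p)
  sup <- support_for_lesion(short, ctx, w$lesion, cfg)
  expect_identical(sup$n_support, 0L)
  expect_identical(sup$n_contradict, 0L)
})

test_that("validation across independent read sets requires both to support", {
  w <- deletion_world()
  ctx <- list(seq = w$locus$seq, pos = w$lesion$locus_pos)
  mut <- simulate_reads(w$locus$seq, depth = 8, read_len = 100,
                        seed = 7)$reads
  ref <- simulate_reads(w$wild, depth = 8, read_len = 100, seed = 8)$reads
  both <- support_for_lesion(list(mut, mut), ctx, w$lesion, cfg)
  expect_true(both$validated)
  expect_identical(both$n_readsets_supporting, 2L)
  one <- support_for_lesion(list(mut, ref), ctx, w$lesion, cfg)
  expect_identical(one$n_readsets_supporting, 1L)
  expect_false(one$validated)  # two sets supplied, only one supports
})

test_that("context shorter than the flanks is an error", {
  w <- deletion_world()
  expect_error(support_for_lesion("ACGT", list(seq = "ACGTACGT", pos = 2),
                                  w$lesion, cfg), "flank")
})

rna_structure <- function() {
  m <- toy_model()
  gene_structure(m$genomic_seq, m$exons)
}

test_that("RNA reads are classified by their splicing content", {
  gs <- rna_structure()
  ## junction-spanning read from the spliced transcript: mature
  tr <- gs$transcript
  junction_read <- substr(tr, 121 - 40, 121 + 39)  # straddles exon1|exon2
  expect_identical(classify_rna_read(junction_read, gs, cfg)$klass,
                   "mature")
  ## read running 30 nt into intron 1: immature
  don <- gs$exons[1, 2]
  intron_read <- substr(gs$locus_seq, don - 69, don + 30)
  out <- classify_rna_read(intron_read, gs, cfg)
  expect_identical(out$klass, "immature")
  expect_gte(out$intronic_overlap, 30L)
  ## short read fully inside exon 2: mature
  exon_read <- substr(gs$locus_seq, gs$exons[2, 1] + 11,
                      gs$exons[2, 1] + 30)
  expect_identical(classify_rna_read(exon_read, gs, cfg)$klass, "mature")
})

test_that("classification is symmetric under reverse complement", {
  gs <- rna_structure()
  reads <- simulate_reads(gs, depth = 2, read_len = 80, error_rate = 0,
                          mature_fraction = 0.5, seed = 12)
  for (r in reads$reads[1:12]) {
    k1 <- classify_rna_read(r, gs, cfg)$klass
    k2 <- classify_rna_read(vestige:::revcomp(r), gs, cfg)$klass
    expect_identical(k1, k2)
  }
})

test_that("expression evidence counts match simulator truth", {
  gs <- rna_structure()
  sim <- simulate_reads(gs, depth = 9, read_len = 100, error_rate = 0,
                        mature_fraction = 0.7, seed = 13)
  counts <- count_expression_evidence(list(toyA = unname(sim$reads)),
                                      list(toyA = gs), cfg)
  expect_identical(counts$total, length(sim$reads))
  expect_identical(counts$mature, sum(sim$truth$class == "mature"))
  expect_identical(counts$immature, sum(sim$truth$class == "immature"))

  ## genes without reads are reported with zero counts
  z <- count_expression_evidence(list(), list(toyA = gs), cfg)
  expect_identical(z$total, 0L)
  expect_identical(z$mature, 0L)
})

test_that("paralog assignment requires a clear mismatch margin", {
  set.seed(14)
  a <- random_seq(400)
  ## candidate B at ~5% divergence from A
  b <- local({
    ch <- strsplit(a, "")[[1]]
    i <- which(runif(length(ch)) < 0.05)
    ch[i] <- vapply(ch[i], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste0(ch, collapse = "")
  })
  read_a <- substr(a, 101, 200)
  expect_identical(assign_read_to_paralog(read_a, c(A = a, B = b), cfg)
                   %in% c("A", "ambiguous"), TRUE)
  ## identical candidates always tie
  expect_identical(assign_read_to_paralog(read_a, c(A = a, B = a), cfg),
                   "ambiguous")
  ## a read with many private mismatches to one candidate is assigned
  expect_identical(assign_read_to_paralog(substr(b, 51, 170),
                                          c(A = a, B = b), cfg), "B")
})

test_that("most unambiguous assignments from a 5% paralog pair are correct", {
  set.seed(15)
  a <- random_seq(600)
  b <- local({
    ch <- strsplit(a, "")[[1]]
    i <- which(runif(length(ch)) < 0.05)
    ch[i] <- vapply(ch[i], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste0(ch, collapse = "")
  })
  n_ok <- 0L; n_called <- 0L
  for (k in 1:40) {
    origin <- sample(c("A", "B"), 1)
    tpl <- if (origin == "A") a else b
    s <- sample(1:(nchar(tpl) - 100), 1)
    call <- assign_read_to_paralog(substr(tpl, s, s + 99),
                                   c(A = a, B = b), cfg)
    if (call != "ambiguous") {
      n_called <- n_called + 1L
      if (call == origin) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_called, 20L)
  expect_gte(n_ok / n_called, 0.95)
})
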