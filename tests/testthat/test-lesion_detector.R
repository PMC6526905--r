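cfg <- vestige_config()

## Build alignments + lesions for a target derived from a model by an
## explicit sequence edit.
annotate_seq <- function(model, seq, species = "t") {
  locus <- target_locus(species, seq)
  aln <- locate_exons(model, locus, cfg)
  list(aln = aln, lesions = call_lesions(aln, model, locus, cfg),
       locus = locus)
}

test_that("identity alignments reconstruct the reference CDS", {
  m <- toy_model()
  aln <- locate_exons(m, target_locus("self", m$genomic_seq), cfg)
  rec <- reconstruct_cds(aln, m)
  expect_identical(rec$seq, m$cds_seq)
  expect_identical(rec$ref_map, 0:(nchar(m$cds_seq) - 1L))
  expect_true(all(rec$offset == 0L))
})

test_that("a 1-nt deletion shifts the downstream frame through later exons", {
  m <- toy_model()
  g <- m$genomic_seq
  pos <- m$exons[2, 1] + 30L  # inside exon 2
  mut <- paste0(substr(g, 1, pos), substr(g, pos + 2, nchar(g)))
  res <- annotate_seq(m, mut)
  rec <- reconstruct_cds(res$aln, m)
  expect_identical(nchar(rec$seq), nchar(m$cds_seq) - 1L)
  in3 <- rec$exon == 3
  expect_true(all(rec$offset[in3] == -1L))
})

test_that("a 5-nt insertion leaves a net +2 frame offset downstream", {
  m <- toy_model()
  g <- m$genomic_seq
  pos <- m$exons[2, 1] + 30L
  mut <- paste0(substr(g, 1, pos), "ACGTA", substr(g, pos + 1, nchar(g)))
  res <- annotate_seq(m, mut)
  rec <- reconstruct_cds(res$aln, m)
  expect_true(all(rec$offset[rec$exon == 3] %% 3L == 2L))
  ins <- res$lesions[res$lesions$type == "insertion", ]
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$length, 5L)
  expect_true(ins$frameshift)
})

test_that("a reference-identical target yields zero lesions", {
  m <- toy_model()
  expect_identical(nrow(annotate_seq(m, m$genomic_seq)$lesions), 0L)
})

test_that("splice dinucleotide changes are called with both alleles", {
  m <- toy_model()
  g <- m$genomic_seq
  don <- m$exons[1, 2]  # first 2 nt of intron 1
  mut <- g
  substr(mut, don + 1, don + 2) <- "GC"
  les <- annotate_seq(m, mut)$lesions
  expect_identical(les$type, "splice_donor")
  expect_identical(les$ref_allele, "GT")
  expect_identical(les$alt_allele, "GC")
  expect_identical(les$intron, 1L)

  acc <- m$exons[3, 1] - 2L  # last 2 nt of intron 2
  mut2 <- g
  substr(mut2, acc + 1, acc + 2) <- "CT"
  les2 <- annotate_seq(m, mut2)$lesions
  expect_identical(les2$type, "splice_acceptor")
  expect_identical(les2$alt_allele, "CT")
  expect_identical(les2$exon, 3L)
  expect_identical(les2$intron, 2L)
})

test_that("a substitution-created stop is called at its codon coordinate", {
  m <- toy_model()
  g <- m$genomic_seq
  ## overwrite codon 2 of the CDS (cds coords 3..5, inside exon 1)
  pos <- m$exons[1, 1] + 3L
  mut <- g
  substr(mut, pos + 1, pos + 3) <- "TAA"
  les <- annotate_seq(m, mut)$lesions
  stop_call <- les[les$type == "premature_stop", ]
  expect_identical(nrow(stop_call), 1L)
  expect_identical(stop_call$cds_coord, 3L)
  expect_identical(stop_call$alt_allele, "TAA")
  expect_false(stop_call$consequence)
})

test_that("premature stop coordinates agree with a direct codon scan", {
  m <- toy_model()
  tree <- toy_tree()
  for (s in 1:3) {
    cl <- evolve_clade(m, tree, 0.05, seed = 400 + s)
    cl <- inject_lesion(cl, "B", list(type = "premature_stop",
                                      cds_coord = 21L))
    res <- annotate_seq(m, cl$loci[["B"]]$seq, "B")
    rec <- reconstruct_cds(res$aln, m)
    oracle <- first_stop_coord(rec$seq)
    called <- res$lesions[res$lesions$type == "premature_stop", ]
    expect_identical(called$cds_coord[1], oracle)
  }
})

test_that("indel left-normalization matches exhaustive enumeration", {
  ## the canonical repetitive-context case: deleting any A of CAAAT gives
  ## the same sequence; leftmost placement is position 1
  les <- vestige:::lesion_row("s", "g", "deletion", 1, cds_coord = 3,
                              length = 1, ref_allele = "A")
  norm <- normalize_indel(les, "CAAAT")
  oracle <- enumerate_leftmost("CAAAT", "deletion", 3, "A")
  expect_identical(norm$cds_coord, oracle$pos)
  expect_identical(norm$ref_allele, oracle$allele)
  expect_identical(norm$cds_coord, 1L)

  ## non-repetitive context is a fixed point
  les2 <- vestige:::lesion_row("s", "g", "deletion", 1, cds_coord = 2,
                               length = 1, ref_allele = "G")
  expect_identical(normalize_indel(les2, "ACGTA"), les2)

  ## idempotence
  expect_identical(normalize_indel(norm, "CAAAT"), norm)
})

test_that("left-normalization matches enumeration on random repeats", {
  set.seed(21)
  for (k in 1:60) {
    ## repeat-rich reference
    ref <- paste0(sample(c("A", "C", "G", "T", "AA", "CACA", "TTT", "GG"),
                         12, replace = TRUE), collapse = "")
    type <- sample(c("deletion", "insertion"), 1)
    len <- sample(1:3, 1)
    if (type == "deletion") {
      pos <- sample(0:(nchar(ref) - len), 1)
      allele <- substr(ref, pos + 1, pos + len)
      les <- vestige:::lesion_row("s", "g", "deletion", 1, cds_coord = pos,
                                  length = len, ref_allele = allele)
    } else {
      pos <- sample(0:nchar(ref), 1)
      allele <- random_seq(len)
      les <- vestige:::lesion_row("s", "g", "insertion", 1, cds_coord = pos,
                                  length = len, alt_allele = allele)
    }
    norm <- normalize_indel(les, ref)
    oracle <- enumerate_leftmost(ref, type, pos, allele)
    expect_identical(norm$cds_coord, oracle$pos)
    expect_identical(normalize_indel(norm, ref), norm)  # idempotent
  }
})

test_that("frameshift flag follows length mod 3 for injected indels 1-9", {
  m <- toy_model()
  tree <- toy_tree()
  cl0 <- evolve_clade(m, tree, 0.03, seed = 77)
  for (L in 1:9) {
    type <- if (L %% 2 == 0) "insertion" else "deletion"
    spec <- if (type == "deletion")
      list(type = "deletion", cds_coord = 30L + 7L * L, length = L)
    else
      list(type = "insertion", cds_coord = 30L + 7L * L,
           seq = random_seq(L))
    cl <- inject_lesion(cl0, "D", spec)
    les <- annotate_seq(m, cl$loci[["D"]]$seq, "D")$lesions
    ind <- les[les$type %in% c("insertion", "deletion"), ]
    expect_identical(nrow(ind), 1L)
    expect_identical(ind$length, L)
    expect_identical(ind$frameshift, L %% 3L != 0L)
  }
})

test_that("severity and verdict rules codify the worked cases", {
  m <- toy_model()  # CDS 360 nt, terminal region starts at 324
  mk <- function(...) vestige:::lesion_row("s", m$gene_id, ...)

  ## premature stop at 20% of the CDS: strong, inactivated
  st <- classify_gene(mk("premature_stop", 1, cds_coord = 72), model = m,
                      config = cfg, species = "s")
  expect_identical(st$lesions$severity, "strong")
  expect_identical(st$verdict, "inactivated")

  ## 4-nt deletion in the last exon close to the stop: weak, inconclusive
  st <- classify_gene(mk("deletion", 3, cds_coord = 350, length = 4,
                         ref_allele = "ACGT"), model = m, config = cfg,
                      species = "s")
  expect_identical(st$lesions$severity, "weak")
  expect_identical(st$verdict, "inconclusive")

  ## a single splice-site lesion alone cannot settle the coding status
  st <- classify_gene(mk("splice_acceptor", 2, intron = 1, cds_coord = 120,
                         ref_allele = "AG", alt_allele = "CT"),
                      model = m, config = cfg, species = "s")
  expect_identical(st$lesions$severity, "medium")
  expect_identical(st$verdict, "inconclusive")

  ## two splice lesions together do
  st <- classify_gene(rbind(
    mk("splice_acceptor", 2, intron = 1, cds_coord = 120,
       ref_allele = "AG", alt_allele = "CT"),
    mk("splice_donor", 2, intron = 2, cds_coord = 270,
       ref_allele = "GT", alt_allele = "GA")), model = m, config = cfg,
    species = "s")
  expect_identical(st$verdict, "inactivated")

  ## non-terminal exon deletion is strong; last-exon deletion is weak
  st <- classify_gene(mk("exon_deletion", 2, cds_coord = 120, length = 150),
                      missing_exons = 2L, model = m, config = cfg,
                      species = "s")
  expect_identical(st$verdict, "inactivated")
  st <- classify_gene(mk("exon_deletion", 3, cds_coord = 270, length = 90),
                      missing_exons = 3L, model = m, config = cfg,
                      species = "s")
  expect_identical(st$verdict, "inconclusive")

  ## no lesions and no missing exons: intact; an assembly gap alone is not
  st <- classify_gene(empty_lesions(), model = m, config = cfg,
                      species = "s")
  expect_identical(st$verdict, "intact")
  st <- classify_gene(empty_lesions(), gap_exons = 2L, model = m,
                      config = cfg, species = "s")
  expect_identical(st$verdict, "inconclusive")
})

test_that("a stop upstream of a critical interval is always strong", {
  m <- toy_model()
  m$critical_intervals <- list(c(330L, 345L))  # motif inside the last exon
  ## stop in the terminal region would otherwise be weak
  les <- vestige:::lesion_row("s", m$gene_id, "premature_stop", 3,
                              cds_coord = 327)
  st <- classify_gene(les, model = m, config = cfg, species = "s")
  expect_identical(st$lesions$severity, "strong")
  expect_identical(st$verdict, "inactivated")
})

test_that("lesion-free divergence is classified intact in every leaf", {
  m <- toy_model()
  tree <- toy_tree()
  for (s in 1:5) {
    cl <- evolve_clade(m, tree, 0.05, seed = 600 + s)
    ann <- run_annotate(m, cl$loci, cfg)
    expect_identical(nrow(ann$lesions), 0L)
    expect_true(all(vapply(ann$statuses, `[[`, "", "verdict") == "intact"))
  }
})
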