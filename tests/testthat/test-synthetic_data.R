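test_that("toy gene models satisfy every structural constraint", {
  m <- make_toy_gene(3, c(120, 150, 90), c(200, 200), seed = 1)
  expect_identical(nchar(m$cds_seq), 360L)
  expect_identical(exon_lengths(m), c(120L, 150L, 90L))
  g <- m$genomic_seq
  for (i in 1:2) {
    don <- substr(g, m$exons[i, 2] + 1, m$exons[i, 2] + 2)
    acc <- substr(g, m$exons[i + 1, 1] - 1, m$exons[i + 1, 1])
    expect_identical(don, "GT")
    expect_identical(acc, "AG")
  }
  ## terminal stop, no internal stops (new_gene_model would refuse)
  expect_true(substr(m$cds_seq, 358, 360) %in% c("TAA", "TAG", "TGA"))

  ## a single-exon model is accepted and intronless
  m1 <- make_toy_gene(1, 99, integer(), seed = 2)
  expect_identical(nrow(m1$exons), 1L)
})

test_that("toy gene generation is deterministic and validates inputs", {
  expect_identical(make_toy_gene(2, c(60, 60), 50, seed = 7),
                   make_toy_gene(2, c(60, 60), 50, seed = 7))
  expect_error(make_toy_gene(2, c(60, 61), 50, seed = 1), "multiple of 3")
  expect_error(make_toy_gene(2, c(60, 60), 5, seed = 1), ">= 8")
})

test_that("zero-rate evolution returns the reference in every leaf", {
  m <- toy_model()
  cl <- evolve_clade(m, toy_tree(), 0, seed = 1)
  for (l in cl$loci) expect_identical(l$seq, m$genomic_seq)
})

test_that("pairwise divergence tracks the expected substitution load", {
  m <- toy_model()
  tree <- toy_tree()
  cl <- evolve_clade(m, tree, 0.05, seed = 4)
  ## leaf-vs-reference: root-to-leaf path length is 1.0, so ~5% of mutable
  ## sites differ (protected sites and back-mutations shave a little off)
  ref <- strsplit(m$genomic_seq, "")[[1]]
  divs <- vapply(cl$loci, function(l)
    mean(strsplit(l$seq, "")[[1]] != ref), 0)
  expect_true(all(divs > 0.02 & divs < 0.08))
  ## sister leaves (path 0.6) are closer than opposite-clade pairs (path 2)
  d_ab <- mean(strsplit(cl$loci[["A"]]$seq, "")[[1]] !=
                 strsplit(cl$loci[["B"]]$seq, "")[[1]])
  d_ah <- mean(strsplit(cl$loci[["A"]]$seq, "")[[1]] !=
                 strsplit(cl$loci[["H"]]$seq, "")[[1]])
  expect_lt(d_ab, d_ah)
})

test_that("evolution with a fixed seed is byte-identical", {
  m <- toy_model()
  c1 <- evolve_clade(m, toy_tree(), 0.05, seed = 9)
  c2 <- evolve_clade(m, toy_tree(), 0.05, seed = 9)
  expect_identical(lapply(c1$loci, `[[`, "seq"),
                   lapply(c2$loci, `[[`, "seq"))
})

test_that("injected lesions are inherited by exactly the descendant leaves", {
  m <- toy_model()
  tree <- toy_tree()
  cl <- evolve_clade(m, tree, 0.03, seed = 5)
  cl <- inject_lesion(cl, c("E", "F"),
                      list(type = "deletion", cds_coord = 45L, length = 1L))
  expect_identical(sort(unique(cl$truth$species)), c("E", "F"))
  cl <- inject_lesion(cl, "B", list(type = "insertion", cds_coord = 200L,
                                    seq = "TT"))
  expect_identical(cl$truth$species[cl$truth$type == "insertion"], "B")
  ## the sequences of non-carriers are untouched by the second injection
  cl2 <- evolve_clade(m, tree, 0.03, seed = 5)
  expect_identical(cl$loci[["H"]]$seq, cl2$loci[["H"]]$seq)
})

test_that("overlapping injections on a shared lineage are rejected", {
  m <- toy_model()
  cl <- evolve_clade(m, toy_tree(), 0.03, seed = 6)
  cl <- inject_lesion(cl, "A", list(type = "deletion", cds_coord = 45L,
                                    length = 1L))
  expect_error(inject_lesion(cl, "A", list(type = "deletion",
                                           cds_coord = 45L, length = 1L)),
               "overlapping injection")
  ## same coordinates on a disjoint lineage are fine
  expect_no_error(inject_lesion(cl, "B", list(type = "deletion",
                                              cds_coord = 45L,
                                              length = 1L)))
})

test_that("N-masking creates a gap_unresolved exon in the masked leaf", {
  m <- toy_model()
  cl <- evolve_clade(m, toy_tree(), 0.03, seed = 8)
  cl <- inject_lesion(cl, "C", list(type = "n_mask", exon = 2L))
  aln <- locate_exons(m, cl$loci[["C"]], vestige_config())
  expect_identical(aln[[2]]$status, "gap_unresolved")
  expect_identical(nrow(cl$truth), 0L)  # masking is not a lesion
  expect_identical(cl$masked[["C"]], 2L)
})

test_that("error-free reads over a lesion all carry the mutant allele", {
  m <- toy_model()
  cl <- evolve_clade(m, toy_tree(), 0, seed = 2)
  cl <- inject_lesion(cl, "A", list(type = "premature_stop",
                                    cds_coord = 90L))
  locus <- cl$loci[["A"]]
  sim <- simulate_reads(locus$seq, depth = 20, read_len = 80, seed = 3)
  g <- vestige:::apply_offset(cl$offsets[["A"]],
                              m$exons[1, 1] + 90L)
  sig <- substr(locus$seq, g - 19, g + 23)  # mutant allele + 20 nt flanks
  over <- sim$truth$start <= (g - 20) & (sim$truth$start + 80) >= (g + 23)
  hits <- vapply(sim$reads, function(r)
    grepl(sig, r, fixed = TRUE) ||
      grepl(sig, vestige:::revcomp(r), fixed = TRUE), logical(1))
  expect_true(all(hits[over]))
  expect_gt(sum(over), 5)
})

test_that("read simulation is deterministic and honours its contracts", {
  tpl <- random_seq(400)
  s1 <- simulate_reads(tpl, depth = 5, read_len = 60, error_rate = 0.01,
                       seed = 4)
  s2 <- simulate_reads(tpl, depth = 5, read_len = 60, error_rate = 0.01,
                       seed = 4)
  expect_identical(s1$reads, s2$reads)
  expect_error(simulate_reads(tpl, depth = 1, read_len = 500, seed = 1),
               "read_len")
  gs <- gene_structure(toy_model()$genomic_seq, toy_model()$exons)
  rna <- simulate_reads(gs, depth = 3, read_len = 90, mature_fraction = 1,
                        seed = 5)
  expect_true(all(rna$truth$class == "mature"))
})

test_that("FASTQ output round-trips through a standard parser", {
  tpl <- random_seq(300)
  sim <- simulate_reads(tpl, depth = 2, read_len = 50, seed = 6)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, f)
  back <- Biostrings::readDNAStringSet(f, format = "fastq")
  expect_identical(as.character(back), sim$reads)
})
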