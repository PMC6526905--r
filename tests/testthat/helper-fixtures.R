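## Programmatic fixtures shared across test files.

## A hand-built 3-exon gene with known sequence content: CDS is
## ATG + GCT x5 + TAA (21 nt) split into exons of 6, 9 and 6 nt.
tiny_gene_parts <- function() {
  list(exon_seqs = c("ATGGCT", "GCTGCTGCT", "GCTTAA"),
       introns = c("GTAAACAG", "GTTTTCAG"),
       flank5 = "CCCCC", flank3 = "GGGGG")
}

tiny_gene_fasta_gff <- function(dir, strand = "+") {
  p <- tiny_gene_parts()
  plus_seq <- paste0(p$flank5, p$exon_seqs[1], p$introns[1], p$exon_seqs[2],
                     p$introns[2], p$exon_seqs[3], p$flank3)
  ## 0-based half-open exon coordinates on the plus strand
  starts0 <- c(5L, 5L + 6L + 8L, 5L + 6L + 8L + 9L + 8L)
  ends0 <- starts0 + c(6L, 9L, 6L)
  L <- nchar(plus_seq)
  if (strand == "+") {
    seq_out <- plus_seq
    g_starts <- starts0 + 1L  # GFF3 1-based closed
    g_ends <- ends0
  } else {
    seq_out <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus_seq)))
    g_starts <- L - ends0 + 1L
    g_ends <- L - starts0
  }
  fa <- file.path(dir, paste0("tiny_", strand, ".fa"))
  writeLines(c(">chr1", seq_out), fa)
  rows <- sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=cds%d;Parent=g1",
                  g_starts, g_ends, strand, seq_along(g_starts))
  gff <- file.path(dir, paste0("tiny_", strand, ".gff3"))
  writeLines(c("##gff-version 3", rows), gff)
  list(fasta = fa, gff3 = gff, cds = "ATGGCTGCTGCTGCTGCTTAA")
}

## Standard simulated study system: 3-exon gene, 8-leaf ultrametric tree of
## unit root-to-leaf depth.
toy_model <- function(seed = 1) {
  make_toy_gene(3, c(120, 150, 90), c(200, 200), seed = seed)
}

toy_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3):0.4,",
    "((E:0.3,F:0.3):0.3,(G:0.3,H:0.3):0.3):0.4);"))
}

## The six-lesion world used by the end-to-end tests: one deletion on the
## stem (all leaves), a premature stop upstream of it on the (C,D) stem, and
## four lesions on other branches.
six_lesion_world <- function(model, tree, subs = 0.05, seed = 1) {
  cl <- evolve_clade(model, tree, subs, seed = seed)
  cl <- inject_lesion(cl, tree$tip.label,
                      list(type = "deletion", cds_coord = 60L, length = 1L))
  cl <- inject_lesion(cl, c("C", "D"),
                      list(type = "premature_stop", cds_coord = 12L))
  cl <- inject_lesion(cl, "A",
                      list(type = "insertion", cds_coord = 150L,
                           seq = "ACGTA"))
  cl <- inject_lesion(cl, "E", list(type = "splice_donor", intron = 1L))
  cl <- inject_lesion(cl, c("G", "H"),
                      list(type = "splice_acceptor", intron = 2L))
  cl <- inject_lesion(cl, "F", list(type = "exon_deletion", exon = 2L))
  cl
}

## Canonical comparable representation of a lesion set.
lesion_keys <- function(lesions) {
  sort(paste(lesions$species, lesions$type, lesions$exon, lesions$cds_coord,
             lesions$length, lesions$alt_allele))
}
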