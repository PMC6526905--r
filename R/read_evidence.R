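## Best glocal alignment of a read against a template, trying both
## orientations; identity is exact matches / read length.
best_read_alignment <- function(read, template, config) {
  fwd <- align_exon(read, template, config)
  rev <- align_exon(revcomp(read), template, config)
  if (rev$score > fwd$score) {
    rev$orientation <- "-"
    rev
  } else {
    fwd$orientation <- "+"
    fwd
  }
}

#' Count read support for a genomic lesion
#'
#' A read supports a lesion when it contains the mutant allele with at least
#' `min_flank` exactly matching nucleotides on both sides, and contradicts
#' it when the same holds for the reference allele swapped into the same
#' locus context. Reads are searched in both orientations; reads ending
#' inside a flank count in neither bucket. With two or more independent read
#' sets, validation additionally requires supporting reads from at least
#' `min_readsets` sets, mirroring validation against independent sequencing
#' projects.
#'
#' @param reads Character vector of reads, or a list of such vectors (one
#'   per independent read set).
#' @param locus_context List with `seq` (the target locus, which carries the
#'   mutant allele) and `pos` (0-based position of the lesion on it).
#' @param lesion One-row lesion data frame.
#' @param config A [vestige_config()].
#' @return List of class `read_support`: `n_support`, `n_contradict`,
#'   `n_readsets_supporting`, `validated`.
#' @export
support_for_lesion <- function(reads, locus_context, lesion,
                               config = vestige_config()) {
  if (!is.list(reads)) reads <- list(reads)
  seq <- toupper(locus_context$seq)
  pos <- as.integer(locus_context$pos)
  flank <- config$min_flank
  alt <- toupper(lesion$alt_allele)
  ref <- toupper(lesion$ref_allele)
  if (lesion$type %in% c("deletion", "exon_deletion")) alt <- ""
  if (lesion$type == "insertion") ref <- ""
  if (pos < flank || pos + nchar(alt) + flank > nchar(seq))
    stop("locus context too short: need ", flank,
         " nt of flank on both sides of the lesion")
  left <- subseq0(seq, pos - flank, pos)
  right <- subseq0(seq, pos + nchar(alt), pos + nchar(alt) + flank)
  mut_sig <- paste0(left, alt, right)
  ref_sig <- paste0(left, ref, right)
  hit <- function(read, sig) {
    grepl(sig, read, fixed = TRUE) || grepl(sig, revcomp(read), fixed = TRUE)
  }
  per_set <- lapply(reads, function(set) {
    set <- toupper(set)
    c(support = sum(vapply(set, hit, logical(1), sig = mut_sig)),
      contradict = sum(vapply(set, hit, logical(1), sig = ref_sig)))
  })
  n_support <- as.integer(sum(vapply(per_set, `[[`, 0, "support")))
  n_contradict <- as.integer(sum(vapply(per_set, `[[`, 0, "contradict")))
  n_sets <- sum(vapply(per_set, function(x) x[["support"]] > 0, logical(1)))
  need_sets <- if (length(reads) >= 2L) config$min_readsets else 1L
  structure(list(n_support = n_support, n_contradict = n_contradict,
                 n_readsets_supporting = n_sets,
                 validated = n_support >= config$min_supporting_reads &&
                   n_sets >= need_sets),
            class = "read_support")
}

#' @export
print.read_support <- function(x, ...) {
  cat(sprintf("read support: %d supporting / %d contradicting (%d set(s)); %s\n",
              x$n_support, x$n_contradict, x$n_readsets_supporting,
              if (x$validated) "validated" else "not validated"))
  invisible(x)
}

#' Target gene structure for RNA read classification
#'
#' @param locus_seq Genomic sequence of the target locus.
#' @param exons Integer matrix of found exon intervals on the locus
#'   (0-based half-open), e.g. from [exon_alignment_table()].
#' @return List of class `gene_structure` with the unspliced locus, the
#'   exon intervals and the spliced transcript.
#' @export
gene_structure <- function(locus_seq, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  transcript <- paste0(vapply(seq_len(nrow(exons)), function(i)
    subseq0(locus_seq, exons[i, 1], exons[i, 2]), ""), collapse = "")
  structure(list(locus_seq = toupper(locus_seq), exons = exons,
                 transcript = transcript), class = "gene_structure")
}

#' Classify an RNA read as maturely or immaturely spliced
#'
#' The read is aligned both to the spliced transcript and to the unspliced
#' locus (both orientations). A read whose best placement is genomic and
#' covers at least `min_intronic_overlap` intronic nucleotides is immature
#' (it retains intronic sequence); a read placed at least as well on the
#' transcript — exonic-only or spanning a splice junction — is mature; reads
#' below the identity floor on both templates, or tied placements that do
#' overlap introns, are ambiguous.
#'
#' @param read Read sequence.
#' @param structure A [gene_structure()].
#' @param config A [vestige_config()].
#' @return List with `klass` (`mature` / `immature` / `ambiguous`),
#'   `intronic_overlap` (nt) and `identity` of the best placement.
#' @export
classify_rna_read <- function(read, structure, config = vestige_config()) {
  read <- toupper(read)
  at <- best_read_alignment(read, structure$transcript, config)
  ag <- best_read_alignment(read, structure$locus_seq, config)
  iv <- ag$interval
  exonic <- 0L
  for (i in seq_len(nrow(structure$exons))) {
    exonic <- exonic + max(0L, min(iv[2], structure$exons[i, 2]) -
                                max(iv[1], structure$exons[i, 1]))
  }
  intronic <- max(0L, (iv[2] - iv[1]) - exonic)
  best_id <- max(at$identity, ag$identity)
  klass <- if (best_id < config$identity_floor) {
    "ambiguous"
  } else if (ag$score > at$score && intronic >= config$min_intronic_overlap) {
    "immature"
  } else if (at$score >= ag$score || intronic < config$min_intronic_overlap) {
    if (at$score == ag$score && intronic >= config$min_intronic_overlap)
      "ambiguous" else "mature"
  } else {
    "ambiguous"
  }
  list(klass = klass, intronic_overlap = as.integer(intronic),
       identity = best_id)
}

#' Tabulate expression evidence per gene
#'
#' @param reads_by_gene Named list: per gene, a character vector of reads
#'   already assigned to that gene.
#' @param structures Named list of [gene_structure()] objects, same names.
#' @param config A [vestige_config()].
#' @return Data frame with `gene_id`, `mature`, `immature`, `ambiguous`,
#'   `total`; genes with zero reads are reported with zero counts.
#' @export
count_expression_evidence <- function(reads_by_gene, structures,
                                      config = vestige_config()) {
  genes <- names(structures)
  rows <- lapply(genes, function(g) {
    reads <- reads_by_gene[[g]]
    if (is.null(reads) || length(reads) == 0L)
      return(data.frame(gene_id = g, mature = 0L, immature = 0L,
                        ambiguous = 0L, total = 0L,
                        stringsAsFactors = FALSE))
    klass <- vapply(reads, function(r)
      classify_rna_read(r, structures[[g]], config)$klass, "")
    data.frame(gene_id = g,
               mature = sum(klass == "mature"),
               immature = sum(klass == "immature"),
               ambiguous = sum(klass == "ambiguous"),
               total = length(klass), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign a read to one of several paralogous genes
#'
#' The read is aligned to every candidate template (both orientations) and
#' assigned to the one with the fewest mismatching positions; the assignment
#' is reported `"ambiguous"` when the best and second-best candidates tie or
#' differ by fewer than `paralog_margin` mismatches, so that reads from a
#' recently duplicated paralog are not silently misattributed.
#'
#' @param read Read sequence.
#' @param candidates Named character vector (or list) of candidate template
#'   sequences (at least two).
#' @param config A [vestige_config()].
#' @return The winning candidate name, or `"ambiguous"`.
#' @export
assign_read_to_paralog <- function(read, candidates,
                                   config = vestige_config()) {
  stopifnot(length(candidates) >= 2L, !is.null(names(candidates)))
  read <- toupper(read)
  mism <- vapply(candidates, function(tpl) {
    a <- best_read_alignment(read, toupper(tpl), config)
    nchar(read) - sum(a$ops$len[a$ops$op == "M"])
  }, 0)
  ord <- order(mism)
  if (mism[ord[2L]] - mism[ord[1L]] < config$paralog_margin)
    return("ambiguous")
  names(candidates)[ord[1L]]
}
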