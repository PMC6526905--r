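#' Run configuration
#'
#' Collects every tunable threshold and score used by the pipeline in one
#' validated list, so that each run is reproducible from its configuration
#' echo alone.
#'
#' @param match,mismatch Alignment scores for identical / differing bases.
#'   Ambiguity codes (including N) never match and always score `mismatch`.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers); a gap
#'   of length L costs `gap_open + L * gap_extend`.
#' @param min_identity,min_coverage Minimum per-exon identity and coverage
#'   (fractions of exon length) for an exon to be called found.
#' @param gap_n_fraction Fraction of a search window that must be N for an
#'   unplaced exon to be reported as `gap_unresolved` rather than `missing`.
#' @param terminal_fraction Fraction of the CDS 3' end regarded as the
#'   carboxyl-terminal region, where truncating lesions are down-weighted.
#' @param stop_flank_identity Minimum identity of the 10 nt on each side of a
#'   substitution-created stop codon for the stop to be called.
#' @param min_flank Exact-match flank (nt) required on both sides of an
#'   allele for a read to count as supporting or contradicting it.
#' @param min_supporting_reads Reads carrying the mutant allele needed to
#'   validate a lesion.
#' @param min_readsets Independent read sets that must each contribute at
#'   least one supporting read when two or more sets are supplied.
#' @param min_intronic_overlap Intronic nucleotides a read must cover to be
#'   classified immature.
#' @param identity_floor Minimum alignment identity for an RNA read to be
#'   classified at all.
#' @param paralog_margin Minimum mismatch-count margin between best and
#'   second-best paralog for an unambiguous read assignment.
#' @param coord_jitter Signature-matching coordinate tolerance in nt;
#'   0 (the default) requires exact equality after left-normalization.
#' @param noncanonical_donors Donor dinucleotides additionally accepted as
#'   functional (e.g. `"GC"` to tolerate minor-class GC-AG introns). Empty by
#'   default: GT is the only canonical donor.
#' @param seed Integer seed recorded with the run.
#'
#' @return A list of class `vestige_config`.
#' @examples
#' cfg <- vestige_config(min_identity = 0.6)
#' cfg$min_identity
#' @export
vestige_config <- function(match = 2, mismatch = -3,
                           gap_open = 5, gap_extend = 2,
                           min_identity = 0.5, min_coverage = 0.5,
                           gap_n_fraction = 0.2,
                           terminal_fraction = 0.1,
                           stop_flank_identity = 0.7,
                           min_flank = 20L,
                           min_supporting_reads = 2L,
                           min_readsets = 2L,
                           min_intronic_overlap = 10L,
                           identity_floor = 0.8,
                           paralog_margin = 2L,
                           coord_jitter = 0L,
                           noncanonical_donors = character(),
                           seed = 1L) {
  cfg <- list(match = match, mismatch = mismatch,
              gap_open = gap_open, gap_extend = gap_extend,
              min_identity = min_identity, min_coverage = min_coverage,
              gap_n_fraction = gap_n_fraction,
              terminal_fraction = terminal_fraction,
              stop_flank_identity = stop_flank_identity,
              min_flank = as.integer(min_flank),
              min_supporting_reads = as.integer(min_supporting_reads),
              min_readsets = as.integer(min_readsets),
              min_intronic_overlap = as.integer(min_intronic_overlap),
              identity_floor = identity_floor,
              paralog_margin = as.integer(paralog_margin),
              coord_jitter = as.integer(coord_jitter),
              noncanonical_donors = toupper(noncanonical_donors),
              seed = as.integer(seed))
  fracs <- c("min_identity", "min_coverage", "gap_n_fraction",
             "terminal_fraction", "stop_flank_identity", "identity_floor")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a single value in [0, 1]", f))
  }
  for (f in c("match", "mismatch", "gap_open", "gap_extend")) {
    if (!is.finite(cfg[[f]])) stop(sprintf("config score '%s' must be finite", f))
  }
  class(cfg) <- "vestige_config"
  cfg
}

#' @export
print.vestige_config <- function(x, ...) {
  cat("vestige run configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
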