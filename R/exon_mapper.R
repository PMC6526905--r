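## Substitution matrix over the IUPAC DNA alphabet: only identical A/C/G/T
## pairs score `match`; N and every other ambiguity code scores `mismatch`
## against everything (including itself), so N runs carry no signal.
iupac_matrix <- function(config) {
  letters16 <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")
  m <- matrix(config$mismatch, length(letters16), length(letters16),
              dimnames = list(letters16, letters16))
  for (b in c("A", "C", "G", "T")) m[b, b] <- config$match
  m
}

## Run-length alignment operations relative to the reference (pattern):
##   M match, X mismatch, D reference base absent from target,
##   I target base absent from reference.
ops_from_alignment <- function(pat_str, sub_str) {
  p <- strsplit(pat_str, "")[[1]]
  s <- strsplit(sub_str, "")[[1]]
  op <- ifelse(p == "-", "I", ifelse(s == "-", "D",
               ifelse(p == s & p %in% c("A", "C", "G", "T"), "M", "X")))
  r <- rle(op)
  data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

#' Align one reference exon inside a target window (glocal)
#'
#' Affine-gap alignment that is global in the exon and local in the window
#' (the standard "glocal" mode for placing a known exon inside a larger
#' genomic region), computed with [Biostrings::pairwiseAlignment()]. A gap of
#' length L costs `gap_open + L * gap_extend`. Ambiguity codes, including N,
#' never match.
#'
#' @param exon_seq Reference exon sequence (non-empty DNA string).
#' @param window_seq Target search window (non-empty DNA string).
#' @param config A [vestige_config()].
#' @return List with `score`, `interval` (0-based half-open on the window),
#'   `ops` (run-length operations M/X/D/I relative to the exon), `identity`
#'   (exact matches / exon length) and `coverage` (exon bases aligned to
#'   target bases / exon length).
#' @examples
#' cfg <- vestige_config()
#' align_exon("ATGGCT", "CCATGGCTAA", cfg)$interval
#' @export
align_exon <- function(exon_seq, window_seq, config = vestige_config()) {
  stopifnot(nzchar(exon_seq), nzchar(window_seq))
  aln <- Biostrings::pairwiseAlignment(
    exon_seq, window_seq, type = "global-local",
    substitutionMatrix = iupac_matrix(config),
    gapOpening = config$gap_open, gapExtension = config$gap_extend)
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  ops <- ops_from_alignment(pat, sub)
  n_match <- sum(ops$len[ops$op == "M"])
  n_mm <- sum(ops$len[ops$op == "X"])
  n_cols <- sum(ops$len)
  exon_len <- nchar(exon_seq)
  ## identity over all alignment columns (gap columns count against it), so
  ## a gap-riddled spurious placement cannot reach the identity of a clean
  ## one; coverage is the fraction of exon bases aligned to target bases
  list(score = Biostrings::score(aln),
       interval = c(start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
                    end = BiocGenerics::end(Biostrings::subject(aln))),
       ops = ops,
       identity = if (n_cols > 0L) n_match / n_cols else 0,
       coverage = (n_match + n_mm) / exon_len)
}

#' Find maximal N runs within an interval of a locus
#'
#' @param locus_seq DNA string.
#' @param interval 0-based half-open `(start, end)`; defaults to the whole
#'   sequence.
#' @return Integer matrix with columns `start`, `end` (0-based half-open),
#'   one row per maximal N run, sorted by position.
#' @export
detect_assembly_gaps <- function(locus_seq,
                                 interval = c(0L, nchar(locus_seq))) {
  start <- as.integer(interval[1]); end <- as.integer(interval[2])
  stopifnot(start >= 0L, end <= nchar(locus_seq), start <= end)
  sub <- subseq0(locus_seq, start, end)
  isn <- strsplit(sub, "")[[1]] == "N"
  out <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  if (!any(isn)) return(out)
  r <- rle(isn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = start + starts[keep], end = start + ends[keep])
}

ops_score <- function(ops, config) {
  sc <- sum(ops$len[ops$op == "M"]) * config$match +
    sum(ops$len[ops$op == "X"]) * config$mismatch
  gaps <- ops[ops$op %in% c("I", "D"), , drop = FALSE]
  sc - nrow(gaps) * config$gap_open - sum(gaps$len) * config$gap_extend
}

## Remove `lp` leading / `rp` trailing pattern (reference) bases from an
## alignment, returning ops and interval for the unpadded pattern, with the
## score recomputed over the remaining columns.
trim_alignment_pads <- function(aln, lp, rp, config = vestige_config()) {
  cols <- rep(aln$ops$op, aln$ops$len)
  pat_c <- cols %in% c("M", "X", "D")
  tgt_c <- cols %in% c("M", "X", "I")
  pat_cum <- cumsum(pat_c)
  n_pat <- pat_cum[length(cols)]
  keep_from <- if (lp > 0L) match(lp, pat_cum) + 1L else 1L
  keep_to <- if (rp > 0L) match(n_pat - rp, pat_cum) else length(cols)
  keep <- seq.int(keep_from, keep_to)
  tgt_before <- if (keep_from > 1L) sum(tgt_c[seq_len(keep_from - 1L)]) else 0L
  tgt_after <- if (keep_to < length(cols))
    sum(tgt_c[seq.int(keep_to + 1L, length(cols))]) else 0L
  r <- rle(cols[keep])
  aln$ops <- data.frame(op = r$values, len = r$lengths,
                        stringsAsFactors = FALSE)
  aln$interval <- c(aln$interval[1] + tgt_before,
                    aln$interval[2] - tgt_after)
  aln$score <- ops_score(aln$ops, config)
  aln
}

## Prefer a substitution reading over compensating indels: when the aligned
## target span has exactly the exon's length but the DP chose internal
## indels, and aligning without gaps costs no more than the indels' own gap
## penalties, the gapless reading is kept (mutation parsimony: a run of
## substitutions is the simpler explanation than an insertion-deletion pair
## restoring the length).
prefer_substitutions <- function(aln, i, model, locus, w_lo, config) {
  if (!any(aln$ops$op %in% c("I", "D"))) return(aln)
  exon_seq <- subseq0(model$genomic_seq, model$exons[i, 1], model$exons[i, 2])
  width <- aln$interval[2] - aln$interval[1]
  if (width != nchar(exon_seq)) return(aln)
  tgt <- subseq0(locus$seq, w_lo + aln$interval[1], w_lo + aln$interval[2])
  e <- strsplit(exon_seq, "")[[1]]
  t <- strsplit(tgt, "")[[1]]
  m <- e == t & e %in% c("A", "C", "G", "T")
  gapless <- sum(m) * config$match + sum(!m) * config$mismatch
  if (gapless >= aln$score - 2 * (config$gap_open + config$gap_extend)) {
    r <- rle(ifelse(m, "M", "X"))
    aln$ops <- data.frame(op = r$values, len = r$lengths,
                          stringsAsFactors = FALSE)
    aln$score <- gapless
  }
  aln
}

n_fraction <- function(seq) {
  if (!nzchar(seq)) return(0)
  sum(strsplit(seq, "")[[1]] == "N") / nchar(seq)
}

#' Place every reference exon in a target locus
#'
#' Exons are placed in decreasing length order so that long, well-anchored
#' exons constrain the search windows of shorter ones: the window for exon i
#' spans from the end of the nearest already-placed exon with a lower index
#' to the start of the nearest placed exon with a higher index (or the locus
#' edges), which enforces colinearity by construction. Placement runs in two
#' passes, so an exon rejected before its neighbours were anchored is
#' retried inside its final inter-anchor window. A placement counts as found
#' only when its alignment score is positive (it must beat the empty
#' alignment) and both thresholds are met; an exon whose best alignment
#' fails this is reported
#' `missing`, unless at least `gap_n_fraction` of its search window is N, in
#' which case it is `gap_unresolved`: absence of sequence, not absence of the
#' exon, is then the parsimonious reading.
#'
#' @param model Reference [gene model][build_gene_model].
#' @param locus A [target_locus()].
#' @param config A [vestige_config()].
#' @return List of per-exon records (class `exon_alignments`): `exon`
#'   (1-based), `status` (`found` / `missing` / `gap_unresolved`),
#'   `interval` (0-based half-open on the locus, or NULL), `ops`,
#'   `identity`, `coverage`.
#' @export
locate_exons <- function(model, locus, config = vestige_config()) {
  n <- nrow(model$exons)
  lens <- exon_lengths(model)
  L <- nchar(locus$seq)
  res <- vector("list", n)
  placed <- rep(NA_integer_, 2L * n)  # start,end pairs of found exons
  dim(placed) <- c(n, 2L)
  search_window <- function(i) {
    below <- which(!is.na(placed[, 1]) & seq_len(n) < i)
    above <- which(!is.na(placed[, 1]) & seq_len(n) > i)
    lo <- if (length(below)) max(placed[below, 2]) else 0L
    hi <- if (length(above)) min(placed[above, 1]) else L
    c(lo, hi)
  }
  pad <- 10L # homologous reference context anchoring each exon boundary
  try_place <- function(i) {
    w <- search_window(i)
    lp <- min(pad, model$exons[i, 1])
    rp <- min(pad, nchar(model$genomic_seq) - model$exons[i, 2])
    ## the pattern carries `lp`/`rp` bases of reference intron/flank on each
    ## side: the (near-)conserved splice context pins the exon boundaries,
    ## which a boundary-blind DP otherwise misplaces by 1-2 nt around
    ## substitutions near the exon ends
    exon_seq <- subseq0(model$genomic_seq, model$exons[i, 1] - lp,
                        model$exons[i, 2] + rp)
    window <- if (w[2] > w[1]) subseq0(locus$seq, w[1], w[2]) else ""
    if (!nzchar(window)) return(NULL)
    aln <- align_exon(exon_seq, window, config)
    if (sum(aln$ops$len) == 0L || is.na(aln$interval[1])) {
      aln$failed <- TRUE
      return(aln)
    }
    aln <- trim_alignment_pads(aln, lp, rp, config)
    if (sum(aln$ops$len) == 0L) {
      aln$failed <- TRUE
      return(aln)
    }
    exon_len <- model$exons[i, 2] - model$exons[i, 1]
    aln <- prefer_substitutions(aln, i, model, locus, w[1], config)
    n_match <- sum(aln$ops$len[aln$ops$op == "M"])
    n_mm <- sum(aln$ops$len[aln$ops$op == "X"])
    aln$identity <- n_match / sum(aln$ops$len)
    aln$coverage <- (n_match + n_mm) / exon_len
    ## a placement must beat the empty alignment (score > 0): spurious
    ## placements in unrelated sequence score deeply negative under these
    ## scores even when their column identity drifts above 0.5
    if (aln$score > 0 && aln$identity >= config$min_identity &&
        aln$coverage >= config$min_coverage) {
      aln$interval <- aln$interval + w[1]
      aln
    } else {
      aln$failed <- TRUE
      aln
    }
  }
  ## two placement passes in decreasing length order: long exons anchor the
  ## windows of short ones, and exons rejected before their neighbours were
  ## anchored get a second chance inside their final window
  for (pass in 1:2) {
    for (i in order(-lens)) {
      if (!is.na(placed[i, 1])) next
      aln <- try_place(i)
      if (!is.null(aln) && is.null(aln$failed)) {
        placed[i, ] <- aln$interval
        res[[i]] <- list(exon = i, status = "found",
                         interval = unname(aln$interval), ops = aln$ops,
                         target_seq = subseq0(locus$seq, aln$interval[1],
                                              aln$interval[2]),
                         identity = aln$identity, coverage = aln$coverage)
      }
    }
  }
  for (i in which(is.na(placed[, 1]))) {
    w <- search_window(i)
    window <- if (w[2] > w[1]) subseq0(locus$seq, w[1], w[2]) else ""
    aln <- res[[i]]
    status <- if (n_fraction(window) >= config$gap_n_fraction)
      "gap_unresolved" else "missing"
    res[[i]] <- list(exon = i, status = status, interval = NULL, ops = NULL,
                     identity = 0, coverage = 0)
  }
  structure(res, class = "exon_alignments",
            species = locus$species, gene_id = model$gene_id)
}

#' @export
print.exon_alignments <- function(x, ...) {
  cat(sprintf("exon placements for %s in %s:\n", attr(x, "gene_id"),
              attr(x, "species")))
  for (e in x) {
    iv <- if (is.null(e$interval)) "-" else
      sprintf("[%d,%d)", e$interval[1], e$interval[2])
    cat(sprintf("  exon %d: %-14s %-14s identity %.3f coverage %.3f\n",
                e$exon, e$status, iv, e$identity, e$coverage))
  }
  invisible(x)
}

#' Per-exon alignment summary as a data frame
#'
#' @param alignments An `exon_alignments` object from [locate_exons()].
#' @return Data frame with one row per reference exon.
#' @export
exon_alignment_table <- function(alignments) {
  do.call(rbind, lapply(alignments, function(e) {
    data.frame(exon = e$exon, status = e$status,
               start = if (is.null(e$interval)) NA_integer_ else e$interval[1],
               end = if (is.null(e$interval)) NA_integer_ else e$interval[2],
               identity = e$identity, coverage = e$coverage,
               stringsAsFactors = FALSE)
  }))
}
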