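#' Reconstruct the target coding sequence from exon placements
#'
#' Concatenates the aligned target sequence of every found exon in exon
#' order, keeping insertions and omitting deleted reference bases, and
#' tracks for every emitted base its reference CDS coordinate and the
#' cumulative frame offset (net inserted minus deleted bases upstream,
#' including frame shifts contributed by whole missing exons). Missing and
#' gap-unresolved exons contribute no sequence; a missing exon shifts the
#' downstream frame by its length, a gap-unresolved exon is assumed present
#' but unsequenced and leaves the frame untouched.
#'
#' @param alignments `exon_alignments` from [locate_exons()].
#' @param model Reference gene model.
#' @return List with `seq` (virtual CDS), `ref_map` (0-based reference CDS
#'   coordinate per base, NA for insertions), `offset` (frame offset per
#'   base), `is_match` (exact match to reference per base) and `exon`
#'   (1-based source exon per base).
#' @export
reconstruct_cds <- function(alignments, model) {
  offs <- cds_offsets(model)
  lens <- exon_lengths(model)
  chars <- character(0)
  ref_map <- integer(0)
  offset_v <- integer(0)
  is_match <- logical(0)
  exon_v <- integer(0)
  locus_v <- integer(0)
  offset <- 0L
  for (e in alignments) {
    i <- e$exon
    if (e$status == "missing") {
      offset <- offset - lens[i]
      next
    }
    if (e$status != "found") next
    tseq <- strsplit(e$target_seq, "")[[1]]
    ref0 <- offs[i]
    t0 <- e$interval[1]
    tpos <- 0L
    rpos <- 0L
    for (k in seq_len(nrow(e$ops))) {
      op <- e$ops$op[k]; len <- e$ops$len[k]
      if (op %in% c("M", "X")) {
        idx <- tpos + seq_len(len)
        chars <- c(chars, tseq[idx])
        ref_map <- c(ref_map, ref0 + rpos + 0:(len - 1L))
        offset_v <- c(offset_v, rep(offset, len))
        is_match <- c(is_match, rep(op == "M", len))
        exon_v <- c(exon_v, rep(i, len))
        locus_v <- c(locus_v, t0 + idx - 1L)
        tpos <- tpos + len; rpos <- rpos + len
      } else if (op == "D") {
        rpos <- rpos + len
        offset <- offset - len
      } else {  # I
        idx <- tpos + seq_len(len)
        chars <- c(chars, tseq[idx])
        ref_map <- c(ref_map, rep(NA_integer_, len))
        offset <- offset + len
        offset_v <- c(offset_v, rep(offset, len))
        is_match <- c(is_match, rep(FALSE, len))
        exon_v <- c(exon_v, rep(i, len))
        locus_v <- c(locus_v, t0 + idx - 1L)
        tpos <- tpos + len
      }
    }
  }
  list(seq = paste0(chars, collapse = ""), ref_map = ref_map,
       offset = offset_v, is_match = is_match, exon = exon_v,
       locus_pos = locus_v)
}

#' Left-normalize an indel lesion
#'
#' Shifts an insertion or deletion to its leftmost equivalent placement in
#' the reference CDS (the VCF left-alignment convention), so that the same
#' mutation observed in different species acquires an identical signature.
#' Idempotent; lesions of other types are returned unchanged.
#'
#' @param lesion One-row lesion data frame.
#' @param ref_cds Reference CDS string the coordinates refer to.
#' @return The lesion with `cds_coord` and allele updated.
#' @export
normalize_indel <- function(lesion, ref_cds) {
  stopifnot(nrow(lesion) == 1L)
  if (!lesion$type %in% c("insertion", "deletion")) return(lesion)
  p <- lesion$cds_coord
  s <- if (lesion$type == "deletion") lesion$ref_allele else lesion$alt_allele
  len <- nchar(s)
  if (len == 0L) return(lesion)
  refv <- strsplit(ref_cds, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  while (p > 0L && refv[p] == sv[len]) {
    sv <- c(refv[p], sv[-len])
    p <- p - 1L
  }
  lesion$cds_coord <- p
  if (lesion$type == "deletion") {
    lesion$ref_allele <- paste0(sv, collapse = "")
  } else {
    lesion$alt_allele <- paste0(sv, collapse = "")
  }
  lesion
}

lesion_row <- function(species, gene_id, type, exon, intron = NA_integer_,
                       cds_coord, length = 0L, ref_allele = "",
                       alt_allele = "", consequence = FALSE,
                       locus_pos = NA_integer_) {
  frameshift <- type %in% c("insertion", "deletion") && (length %% 3L != 0L)
  data.frame(species = species, gene_id = gene_id, type = type,
             exon = as.integer(exon), intron = as.integer(intron),
             cds_coord = as.integer(cds_coord), length = as.integer(length),
             ref_allele = ref_allele, alt_allele = alt_allele,
             frameshift = frameshift, severity = NA_character_,
             consequence = consequence, locus_pos = as.integer(locus_pos),
             stringsAsFactors = FALSE)
}

exon_of_coord <- function(model, cds_coord) {
  offs <- cds_offsets(model)
  ends <- offs + exon_lengths(model)
  i <- which(cds_coord >= offs & cds_coord < ends)
  if (length(i)) i[1L] else nrow(model$exons)
}

#' Call inactivating lesions from exon placements
#'
#' Emits every alignment indel as an insertion/deletion lesion
#' (left-normalized against the reference CDS), translates the reconstructed
#' virtual CDS and emits premature stop codons, checks the canonical GT / AG
#' dinucleotides at both ends of every target intron flanked by found exons,
#' and reports missing exons as whole-exon deletions. Gap-unresolved exons
#' produce no lesion. A premature stop inside a shifted reading frame is
#' flagged as a `consequence` of the upstream frameshift: it is reported,
#' but the frameshift itself is the heritable signature. A stop created by
#' substitution is only called when the 10 aligned bases on each side reach
#' `stop_flank_identity`, which suppresses stop calls inside alignment noise.
#'
#' @param alignments `exon_alignments` from [locate_exons()].
#' @param model Reference gene model.
#' @param locus The [target_locus()] the alignments refer to.
#' @param config A [vestige_config()].
#' @return Lesion data frame (see [empty_lesions()]), sorted by CDS
#'   coordinate; severity is assigned by [classify_gene()].
#' @export
call_lesions <- function(alignments, model, locus,
                         config = vestige_config()) {
  species <- locus$species
  gene <- model$gene_id
  out <- list()
  offs <- cds_offsets(model)
  lens <- exon_lengths(model)
  n <- nrow(model$exons)

  ## --- alignment indels ------------------------------------------------
  for (e in alignments) {
    if (e$status != "found") next
    i <- e$exon
    rpos <- 0L
    tpos <- 0L
    for (k in seq_len(nrow(e$ops))) {
      op <- e$ops$op[k]; len <- e$ops$len[k]
      if (op == "D") {
        ref_seq <- subseq0(model$cds_seq, offs[i] + rpos, offs[i] + rpos + len)
        les <- lesion_row(species, gene, "deletion", i,
                          cds_coord = offs[i] + rpos, length = len,
                          ref_allele = ref_seq,
                          locus_pos = e$interval[1] + tpos)
        out[[length(out) + 1L]] <- normalize_indel(les, model$cds_seq)
        rpos <- rpos + len
      } else if (op == "I") {
        alt_seq <- subseq0(e$target_seq, tpos, tpos + len)
        les <- lesion_row(species, gene, "insertion", i,
                          cds_coord = offs[i] + rpos, length = len,
                          alt_allele = alt_seq,
                          locus_pos = e$interval[1] + tpos)
        out[[length(out) + 1L]] <- normalize_indel(les, model$cds_seq)
        tpos <- tpos + len
      } else {
        rpos <- rpos + len
        tpos <- tpos + len
      }
    }
  }
  has_frameshift_upstream <- function(coord) {
    any(vapply(out, function(l) l$frameshift && l$cds_coord <= coord,
               logical(1)))
  }

  ## --- premature stop codons -------------------------------------------
  rec <- reconstruct_cds(alignments, model)
  vlen <- nchar(rec$seq)
  first_emitted <- FALSE
  if (vlen >= 3L) {
    for (j in seq_len(vlen %/% 3L)) {
      a <- 3L * (j - 1L) + 1L
      codon <- substr(rec$seq, a, a + 2L)
      if (!codon %in% STOP_CODONS) next
      refc <- rec$ref_map[a:(a + 2L)]
      refc <- refc[!is.na(refc)]
      if (!length(refc)) next
      coord <- min(refc)
      if (coord >= model$stop_coord) break
      off <- rec$offset[a]
      in_frame <- off %% 3L == 0L
      if (in_frame && !first_emitted || in_frame) {
        ## substitution-created (or frame-restored) stop: guard with the
        ## flanking-identity filter
        lo <- max(1L, a - 10L); hi <- min(vlen, a + 2L + 10L)
        left <- if (lo < a) mean(rec$is_match[lo:(a - 1L)]) else 1
        right <- if (hi > a + 2L) mean(rec$is_match[(a + 3L):hi]) else 1
        subst <- !all(rec$is_match[a:(a + 2L)])
        if (subst && (left < config$stop_flank_identity ||
                      right < config$stop_flank_identity)) next
        if (!subst) next  # reference-identical codon cannot be a new stop
        out[[length(out) + 1L]] <-
          lesion_row(species, gene, "premature_stop",
                     exon_of_coord(model, coord), cds_coord = coord,
                     ref_allele = subseq0(model$cds_seq,
                                          coord - coord %% 3L,
                                          coord - coord %% 3L + 3L),
                     alt_allele = codon,
                     consequence = FALSE,
                     locus_pos = rec$locus_pos[a])
        first_emitted <- TRUE
        next
      }
      if (!first_emitted) {
        ## first stop met by the ribosome in the shifted frame: reported as
        ## the consequence of the upstream frameshift
        out[[length(out) + 1L]] <-
          lesion_row(species, gene, "premature_stop",
                     exon_of_coord(model, coord), cds_coord = coord,
                     alt_allele = codon,
                     consequence = has_frameshift_upstream(coord),
                     locus_pos = rec$locus_pos[a])
        first_emitted <- TRUE
      }
    }
  }

  ## --- splice-site dinucleotides ---------------------------------------
  found_iv <- lapply(alignments, function(e)
    if (e$status == "found") e$interval else NULL)
  for (i in seq_len(n - 1L)) {
    if (is.null(found_iv[[i]]) || is.null(found_iv[[i + 1L]])) next
    don_start <- found_iv[[i]][2]
    acc_end <- found_iv[[i + 1L]][1]
    if (acc_end - don_start < 4L) next  # no resolvable intron
    donor <- subseq0(locus$seq, don_start, don_start + 2L)
    acceptor <- subseq0(locus$seq, acc_end - 2L, acc_end)
    junction <- offs[i] + lens[i]
    if (donor != "GT" && !donor %in% config$noncanonical_donors &&
        !grepl("N", donor)) {
      out[[length(out) + 1L]] <-
        lesion_row(species, gene, "splice_donor", exon = i, intron = i,
                   cds_coord = junction, ref_allele = "GT",
                   alt_allele = donor, locus_pos = don_start)
    }
    if (acceptor != "AG" && !grepl("N", acceptor)) {
      out[[length(out) + 1L]] <-
        lesion_row(species, gene, "splice_acceptor", exon = i + 1L,
                   intron = i, cds_coord = junction, ref_allele = "AG",
                   alt_allele = acceptor, locus_pos = acc_end - 2L)
    }
  }

  ## --- whole-exon deletions --------------------------------------------
  for (e in alignments) {
    if (e$status == "missing") {
      i <- e$exon
      prev_found <- Filter(function(x) x$status == "found" && x$exon < i,
                           alignments)
      lp <- if (length(prev_found))
        prev_found[[length(prev_found)]]$interval[2] else NA_integer_
      out[[length(out) + 1L]] <-
        lesion_row(species, gene, "exon_deletion", exon = i,
                   cds_coord = offs[i], length = lens[i], locus_pos = lp)
    }
  }

  if (!length(out)) return(empty_lesions())
  les <- do.call(rbind, out)
  les <- les[order(les$cds_coord, les$type), , drop = FALSE]
  rownames(les) <- NULL
  validate_lesions(les)
  les
}

#' Classify the coding status of a gene in one species
#'
#' Codifies the case-by-case reasoning of pseudogene annotation into an
#' explicit severity scheme. Strong evidence: a frameshift indel or a
#' premature stop lying upstream of the carboxyl-terminal region (the final
#' `terminal_fraction` of the CDS) and outside the last exon, a premature
#' stop upstream of an annotated critical interval (e.g. an active-site
#' motif), or deletion of a non-terminal exon. Medium evidence: a
#' non-canonical splice dinucleotide, which compromises the transcript but
#' can in principle be rescued by cryptic splicing. Weak evidence: a
#' truncating lesion confined to the terminal region or last exon, where
#' selective pressure is lower, or an in-frame indel. Premature stops flagged
#' as consequences of an upstream frameshift are reported but not counted a
#' second time.
#'
#' The verdict is `inactivated` with at least one strong lesion or at least
#' two medium-or-strong lesions; `inconclusive` with exactly one medium
#' lesion, only weak lesions, or only unresolved assembly gaps; `intact`
#' with no lesions, no missing exons and no gaps.
#'
#' @param lesions Lesion data frame from [call_lesions()].
#' @param missing_exons,gap_exons Integer vectors of 1-based exon indices.
#' @param model Reference gene model.
#' @param config A [vestige_config()].
#' @param species Species label for the status; defaults to the species of
#'   the first lesion.
#' @return A `gene_status` object: `species`, `gene_id`, `verdict`,
#'   `lesions` (with severity filled in), `missing_exons`, `gap_exons`.
#' @export
classify_gene <- function(lesions, missing_exons = integer(),
                          gap_exons = integer(), model,
                          config = vestige_config(), species = NULL) {
  if (is.null(species))
    species <- if (nrow(lesions)) lesions$species[1L] else NA_character_
  n_exons <- nrow(model$exons)
  cds_len <- nchar(model$cds_seq)
  cut <- (1 - config$terminal_fraction) * cds_len
  crit <- model$critical_intervals
  upstream_of_critical <- function(coord) {
    !is.null(crit) && any(vapply(crit, function(iv) coord < iv[2], logical(1)))
  }
  sev <- character(nrow(lesions))
  for (k in seq_len(nrow(lesions))) {
    l <- lesions[k, ]
    sev[k] <- switch(
      l$type,
      insertion = ,
      deletion = {
        if (!l$frameshift) "weak"
        else if (l$cds_coord < cut && l$exon < n_exons) "strong"
        else "weak"
      },
      premature_stop = {
        if (upstream_of_critical(l$cds_coord)) "strong"
        else if (l$cds_coord < cut && l$exon < n_exons) "strong"
        else "weak"
      },
      splice_donor = ,
      splice_acceptor = "medium",
      exon_deletion = if (l$exon < n_exons) "strong" else "weak")
  }
  lesions$severity <- sev
  countable <- lesions[!(lesions$type == "premature_stop" &
                           lesions$consequence), , drop = FALSE]
  n_strong <- sum(countable$severity == "strong")
  n_medium <- sum(countable$severity == "medium")
  verdict <- if (n_strong >= 1L || (n_strong + n_medium) >= 2L) {
    "inactivated"
  } else if (nrow(countable) > 0L) {
    "inconclusive"
  } else if (length(gap_exons) > 0L) {
    "inconclusive"
  } else {
    "intact"
  }
  structure(list(species = species,
                 gene_id = model$gene_id, verdict = verdict,
                 lesions = lesions,
                 missing_exons = as.integer(missing_exons),
                 gap_exons = as.integer(gap_exons)),
            class = "gene_status")
}

#' @export
print.gene_status <- function(x, ...) {
  cat(sprintf("%s / %s: %s (%d lesion(s)", x$species, x$gene_id, x$verdict,
              nrow(x$lesions)))
  if (length(x$missing_exons))
    cat(", missing exon(s) ", paste(x$missing_exons, collapse = ","))
  if (length(x$gap_exons))
    cat(", gap exon(s) ", paste(x$gap_exons, collapse = ","))
  cat(")\n")
  invisible(x)
}
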