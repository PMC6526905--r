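CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  all64
}
SENSE_CODONS <- setdiff(CODONS, STOP_CODONS)

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random multi-exon reference gene model
#'
#' Builds a toy gene whose CDS is a random run of sense codons followed by a
#' stop codon (so the reference has no internal in-frame stop by
#' construction), split into exons separated by introns that start with the
#' canonical GT and end with the canonical AG, embedded in random flanking
#' sequence.
#'
#' @param n_exons Number of exons.
#' @param exon_lengths Integer vector of exon lengths (nt, summing to a
#'   multiple of 3, each >= 3).
#' @param intron_lengths Integer vector of `n_exons - 1` intron lengths
#'   (each >= 8).
#' @param seed Integer seed; the same seed yields a byte-identical model.
#' @param gene_id,species Labels stored in the model.
#' @param flank Length of random flanking sequence on each side.
#' @return A `gene_model`.
#' @examples
#' m <- make_toy_gene(3, c(120, 150, 90), c(200, 200), seed = 1)
#' nchar(m$cds_seq)
#' @export
make_toy_gene <- function(n_exons, exon_lengths, intron_lengths, seed,
                          gene_id = "toyA", species = "reference",
                          flank = 150L) {
  if (length(exon_lengths) != n_exons)
    stop("exon_lengths must have length n_exons")
  if (n_exons > 1L && length(intron_lengths) != n_exons - 1L)
    stop("intron_lengths must have length n_exons - 1")
  if (any(exon_lengths < 3L)) stop("exon lengths must be >= 3")
  if (n_exons > 1L && any(intron_lengths < 8L))
    stop("intron lengths must be >= 8")
  total <- sum(exon_lengths)
  if (total %% 3L != 0L) stop("total CDS length must be a multiple of 3")
  set.seed(seed)
  n_codons <- total %/% 3L
  cds <- paste0(c(sample(SENSE_CODONS, n_codons - 1L, replace = TRUE),
                  sample(STOP_CODONS, 1L)), collapse = "")
  introns <- if (n_exons > 1L) {
    vapply(intron_lengths, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), "")
  } else character()
  pieces <- character(2L * n_exons - 1L)
  offs <- cumsum(c(0L, exon_lengths[-n_exons]))
  for (i in seq_len(n_exons)) {
    pieces[2L * i - 1L] <- subseq0(cds, offs[i], offs[i] + exon_lengths[i])
    if (i < n_exons) pieces[2L * i] <- introns[i]
  }
  genomic <- paste0(random_dna(flank), paste0(pieces, collapse = ""),
                    random_dna(flank), collapse = "")
  starts <- flank + offs + cumsum(c(0L, intron_lengths))[seq_len(n_exons)]
  ends <- starts + exon_lengths
  new_gene_model(gene_id, species, genomic, cbind(starts, ends))
}

## genomic positions (0-based) that background substitutions must not touch:
## splice dinucleotides, the start codon, and the terminal stop codon
protected_positions <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  prot <- c(ex[1, 1] + 0:2,                      # start codon
            ex[n, 2] - 3L + 0:2)                 # terminal stop
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      prot <- c(prot, ex[i, 2] + 0:1,            # donor GT
                ex[i + 1L, 1] - 2L + 0:1)        # acceptor AG
    }
  }
  sort(unique(prot))
}

## Apply background point substitutions to one sequence. CDS substitutions
## that would create an in-frame stop codon are resampled (and skipped when
## no alternative base avoids a stop), so background divergence is
## lesion-free by construction.
mutate_sequence <- function(seq, p, model) {
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  prot <- protected_positions(model) + 1L  # 1-based
  in_cds <- rep(FALSE, L)
  codon_start <- integer(L)  # 1-based position of codon start, by CDS pos
  offs <- cds_offsets(model)
  for (i in seq_len(nrow(model$exons))) {
    idx <- (model$exons[i, 1] + 1L):model$exons[i, 2]
    in_cds[idx] <- TRUE
  }
  ## map genomic (1-based) -> CDS coord (0-based)
  g2c <- rep(NA_integer_, L)
  for (i in seq_len(nrow(model$exons))) {
    idx <- (model$exons[i, 1] + 1L):model$exons[i, 2]
    g2c[idx] <- offs[i] + seq_along(idx) - 1L
  }
  c2g <- which(!is.na(g2c))[order(g2c[!is.na(g2c)])]
  hits <- which(runif(L) < p)
  hits <- setdiff(hits, prot)
  bases <- c("A", "C", "G", "T")
  for (h in hits) {
    cur <- chars[h]
    if (!cur %in% bases) next
    alts <- sample(setdiff(bases, cur))
    if (!in_cds[h]) {
      chars[h] <- alts[1L]
      next
    }
    cc <- g2c[h]
    cod0 <- cc - cc %% 3L
    cod_g <- c2g[(cod0 + 1L):(cod0 + 3L)]
    within <- cc %% 3L + 1L
    for (alt in alts) {
      codon <- chars[cod_g]
      codon[within] <- alt
      if (!paste0(codon, collapse = "") %in% STOP_CODONS) {
        chars[h] <- alt
        break
      }
    }
  }
  paste0(chars, collapse = "")
}

#' Evolve a reference locus along a species tree
#'
#' Simulates neutral point substitutions (equal-rate, Jukes-Cantor-like)
#' independently along every branch. Splice dinucleotides, the start codon
#' and the terminal stop are never mutated, and any substitution that would
#' create an in-frame stop codon is resampled, so background divergence
#' introduces no inactivating lesion: every lesion later detected in a
#' simulated clade is an injected one. The background process has no indels;
#' indels enter only through [inject_lesion()].
#'
#' @param model Reference `gene_model`.
#' @param tree `phylo` species tree; edge lengths are used when present,
#'   otherwise every edge has length 1.
#' @param subs_per_site Expected substitutions per site per unit branch
#'   length, in `[0, 0.3]`.
#' @param seed Integer seed.
#' @return A `sim_clade` object holding the per-leaf loci, the (initially
#'   empty) lesion truth table, and bookkeeping for coordinate shifts.
#' @export
evolve_clade <- function(model, tree, subs_per_site, seed) {
  stopifnot(subs_per_site >= 0, subs_per_site <= 0.3)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  elen <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else
    tree$edge.length
  seqs <- vector("list", nnode)
  root <- ntip + 1L
  seqs[[root]] <- model$genomic_seq
  ## process edges top-down: an edge is ready once its parent sequence is
  ## assigned (edge order in the phylo object is otherwise irrelevant)
  done <- rep(FALSE, nrow(tree$edge))
  while (!all(done)) {
    ready <- which(!done & !vapply(tree$edge[, 1], function(n)
      is.null(seqs[[n]]), logical(1)))
    if (!length(ready)) stop("disconnected tree edges")
    for (k in ready) {
      parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
      p <- min(0.75, subs_per_site * elen[k])
      seqs[[child]] <- mutate_sequence(seqs[[parent]], p, model)
      done[k] <- TRUE
    }
  }
  loci <- setNames(lapply(seq_len(ntip), function(i)
    target_locus(tree$tip.label[i], seqs[[i]])), tree$tip.label)
  structure(list(model = model, tree = tree, loci = loci,
                 truth = empty_lesions(),
                 offsets = setNames(
                   rep(list(data.frame(gpos = integer(), delta = integer())),
                       ntip), tree$tip.label),
                 masked = setNames(rep(list(integer()), ntip),
                                   tree$tip.label),
                 edited = setNames(
                   rep(list(data.frame(start = integer(), end = integer())),
                       ntip), tree$tip.label)),
            class = "sim_clade")
}

#' @export
print.sim_clade <- function(x, ...) {
  cat(sprintf("simulated clade: %d leaves, gene '%s', %d injected lesion(s)\n",
              length(x$loci), x$model$gene_id, nrow(x$truth)))
  invisible(x)
}

## leaves descending from the stem above MRCA(branch_leaves)
branch_leaves <- function(tree, branch) {
  stopifnot(all(branch %in% tree$tip.label))
  if (length(branch) == 1L) return(branch)
  node <- ape::getMRCA(tree, branch)
  ape::extract.clade(tree, node)$tip.label
}

apply_offset <- function(offsets, gpos) {
  gpos + sum(offsets$delta[offsets$gpos <= gpos])
}

#' Inject an inactivating lesion on a tree branch
#'
#' Applies one lesion on the branch directly above the MRCA of
#' `branch` (a terminal branch when one leaf is named) so that every
#' descendant leaf inherits it at the homologous position, and records the
#' expected lesion signature in the clade's truth table. Because the
#' background process is indel-free, coordinates of later injections on the
#' same lineage are shifted deterministically by earlier injected indels.
#'
#' Supported `spec$type` values: `insertion` (`cds_coord`, `seq`),
#' `deletion` (`cds_coord`, `length`), `premature_stop` (`cds_coord` on a
#' codon boundary; `alt` defaults to TGA), `splice_donor` / `splice_acceptor`
#' (`intron`; `alt` defaults to GC / CT), `exon_deletion` (`exon`), and
#' `n_mask` (`exon`, optional `margin`) which N-masks the exon's
#' neighbourhood to emulate an assembly gap and adds no lesion to the truth
#' table.
#'
#' For indel and stop injections the 12 nt of context on each side of the
#' edit are restored to the reference bases in every carrier before the edit
#' is applied. This keeps the truth signature well defined: without it, a
#' background substitution immediately adjacent to an injected indel can
#' merge with it into a different (equally optimal) indel representation,
#' and no normalization could recover the injected one. Injections whose
#' context windows would overlap on a shared lineage (closer than about
#' 30 nt) are rejected with an error, as are repeated injections at
#' identical coordinates.
#'
#' @param clade A `sim_clade` from [evolve_clade()].
#' @param branch Character vector of leaf labels; the lesion is placed on
#'   the stem above their MRCA.
#' @param spec Lesion specification (see Details).
#' @return The modified `sim_clade`.
#' @export
inject_lesion <- function(clade, branch, spec) {
  model <- clade$model
  offs <- cds_offsets(model)
  lens <- exon_lengths(model)
  leaves <- branch_leaves(clade$tree, branch)
  type <- spec$type
  ## genomic anchor position (0-based, reference coordinates) and payload
  if (type %in% c("insertion", "deletion", "premature_stop")) {
    cc <- as.integer(spec$cds_coord)
    if (cc < 0L || cc >= nchar(model$cds_seq))
      stop("cds_coord out of range")
    exon <- exon_of_coord(model, cc)
    g <- model$exons[exon, 1] + (cc - offs[exon])
  } else if (type %in% c("splice_donor", "splice_acceptor")) {
    i <- as.integer(spec$intron)
    if (i < 1L || i >= nrow(model$exons)) stop("intron index out of range")
    g <- if (type == "splice_donor") model$exons[i, 2] else
      model$exons[i + 1L, 1] - 2L
  } else if (type %in% c("exon_deletion", "n_mask")) {
    i <- as.integer(spec$exon)
    if (i < 1L || i > nrow(model$exons)) stop("exon index out of range")
    g <- model$exons[i, 1]
  } else stop("unknown lesion type: ", type)

  ## reference-coordinate window this injection edits (context included for
  ## the allele-bearing types); overlapping windows on a shared lineage are
  ## rejected so every truth signature stays independent
  ctx <- 12L
  ref_extent <- switch(type,
    deletion = c(g - ctx, g + spec$length + ctx),
    insertion = c(g - ctx, g + ctx),
    premature_stop = c(g - ctx, g + 3L + ctx),
    splice_donor = ,
    splice_acceptor = c(g, g + 2L),
    exon_deletion = ,
    n_mask = c(model$exons[spec$exon, 1], model$exons[spec$exon, 2]))
  for (leaf in leaves) {
    prev <- clade$edited[[leaf]]
    if (!is.null(prev) && nrow(prev) &&
        any(ref_extent[1] < prev$end & prev$start < ref_extent[2]))
      stop("overlapping injection at identical or adjacent coordinates",
           " (leaf ", leaf, ")")
  }

  restore <- type %in% c("insertion", "deletion", "premature_stop")
  for (leaf in leaves) {
    seq <- clade$loci[[leaf]]$seq
    if (restore) {
      a <- max(0L, ref_extent[1])
      b <- min(nchar(model$genomic_seq), ref_extent[2])
      off <- sum(clade$offsets[[leaf]]$delta[clade$offsets[[leaf]]$gpos < a])
      substr(seq, a + off + 1L, b + off) <- subseq0(model$genomic_seq, a, b)
    }
    ga <- apply_offset(clade$offsets[[leaf]], g)
    if (type == "deletion") {
      L <- as.integer(spec$length)
      seq <- paste0(subseq0(seq, 0L, ga), subseq0(seq, ga + L, nchar(seq)))
      clade$offsets[[leaf]] <- rbind(clade$offsets[[leaf]],
                                     data.frame(gpos = g, delta = -L))
    } else if (type == "insertion") {
      ins <- toupper(spec$seq)
      seq <- paste0(subseq0(seq, 0L, ga), ins, subseq0(seq, ga, nchar(seq)))
      clade$offsets[[leaf]] <- rbind(clade$offsets[[leaf]],
                                     data.frame(gpos = g,
                                                delta = nchar(ins)))
    } else if (type == "premature_stop") {
      if (spec$cds_coord %% 3L != 0L)
        stop("premature_stop cds_coord must be a codon start")
      alt <- toupper(spec$alt %||% "TGA")
      substr(seq, ga + 1L, ga + 3L) <- alt
    } else if (type %in% c("splice_donor", "splice_acceptor")) {
      alt <- toupper(spec$alt %||%
                       if (type == "splice_donor") "GC" else "CT")
      substr(seq, ga + 1L, ga + 2L) <- alt
    } else if (type == "exon_deletion") {
      i <- spec$exon
      ga2 <- apply_offset(clade$offsets[[leaf]], model$exons[i, 2])
      L <- ga2 - ga
      seq <- paste0(subseq0(seq, 0L, ga), subseq0(seq, ga2, nchar(seq)))
      clade$offsets[[leaf]] <- rbind(clade$offsets[[leaf]],
                                     data.frame(gpos = g, delta = -L))
    } else if (type == "n_mask") {
      i <- spec$exon
      m <- as.integer(spec$margin %||% 10L)
      a <- max(0L, apply_offset(clade$offsets[[leaf]],
                                model$exons[i, 1]) - m)
      b <- min(nchar(seq), apply_offset(clade$offsets[[leaf]],
                                        model$exons[i, 2]) + m)
      substr(seq, a + 1L, b) <- paste0(rep("N", b - a), collapse = "")
      clade$masked[[leaf]] <- sort(unique(c(clade$masked[[leaf]], i)))
    }
    clade$loci[[leaf]]$seq <- seq
    clade$edited[[leaf]] <- rbind(clade$edited[[leaf]],
                                  data.frame(start = ref_extent[1],
                                             end = ref_extent[2]))
  }

  if (type != "n_mask") {
    rows <- do.call(rbind, lapply(leaves, function(leaf) {
      les <- switch(type,
        deletion = lesion_row(leaf, model$gene_id, "deletion",
                              exon_of_coord(model, spec$cds_coord),
                              cds_coord = spec$cds_coord,
                              length = spec$length,
                              ref_allele = subseq0(model$cds_seq,
                                                   spec$cds_coord,
                                                   spec$cds_coord +
                                                     spec$length)),
        insertion = lesion_row(leaf, model$gene_id, "insertion",
                               exon_of_coord(model, spec$cds_coord),
                               cds_coord = spec$cds_coord,
                               length = nchar(spec$seq),
                               alt_allele = toupper(spec$seq)),
        premature_stop = lesion_row(leaf, model$gene_id, "premature_stop",
                                    exon_of_coord(model, spec$cds_coord),
                                    cds_coord = spec$cds_coord,
                                    ref_allele = subseq0(model$cds_seq,
                                                         spec$cds_coord,
                                                         spec$cds_coord + 3L),
                                    alt_allele = toupper(spec$alt %||% "TGA")),
        splice_donor = lesion_row(leaf, model$gene_id, "splice_donor",
                                  exon = spec$intron, intron = spec$intron,
                                  cds_coord = offs[spec$intron] +
                                    lens[spec$intron],
                                  ref_allele = "GT",
                                  alt_allele = toupper(spec$alt %||% "GC")),
        splice_acceptor = lesion_row(leaf, model$gene_id, "splice_acceptor",
                                     exon = spec$intron + 1L,
                                     intron = spec$intron,
                                     cds_coord = offs[spec$intron + 1L],
                                     ref_allele = "AG",
                                     alt_allele = toupper(spec$alt %||% "CT")),
        exon_deletion = lesion_row(leaf, model$gene_id, "exon_deletion",
                                   exon = spec$exon,
                                   cds_coord = offs[spec$exon],
                                   length = lens[spec$exon]))
      normalize_indel(les, model$cds_seq)
    }))
    clade$truth <- rbind(clade$truth, rows)
  }
  clade
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected per-species verdicts for a simulated clade
#'
#' Applies the package's own severity and verdict rules to the injected
#' truth lesions of every leaf, yielding the verdict the pipeline is
#' expected to recover from sequence alone.
#'
#' @param clade A `sim_clade`.
#' @param config A [vestige_config()].
#' @return Data frame with `species` and `verdict`.
#' @export
truth_verdicts <- function(clade, config = vestige_config()) {
  do.call(rbind, lapply(names(clade$loci), function(leaf) {
    les <- clade$truth[clade$truth$species == leaf, , drop = FALSE]
    miss <- les$exon[les$type == "exon_deletion"]
    st <- classify_gene(les, missing_exons = miss,
                        gap_exons = clade$masked[[leaf]],
                        model = clade$model, config = config,
                        species = leaf)
    data.frame(species = leaf, verdict = st$verdict,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate sequencing reads from a template or gene structure
#'
#' Genomic mode (`mature_fraction = NULL`): uniform read start positions
#' over a single template sequence. RNA mode (with a [gene_structure()]):
#' each read is drawn from the spliced transcript with probability
#' `mature_fraction` (a maturely spliced molecule) or from the unspliced
#' pre-mRNA (first to last exon) otherwise, and its true class is recorded.
#' Because read classes are defined by read content (an immature read is one
#' containing intronic sequence), immature reads are drawn only from
#' pre-mRNA positions that cover at least `min_intronic_overlap` intronic
#' nucleotides: a pre-mRNA read lying entirely inside one exon is
#' indistinguishable from a mature read by any content-based definition.
#' Sequencing errors are independent per-base substitutions; reads are
#' emitted from either strand with equal probability.
#'
#' @param template A DNA string (genomic mode) or a [gene_structure()]
#'   (RNA mode).
#' @param depth Mean coverage depth (> 0).
#' @param read_len Read length (nt).
#' @param error_rate Per-base substitution error rate, in `[0, 0.05]`.
#' @param mature_fraction Probability a read derives from the spliced
#'   transcript (RNA mode only).
#' @param min_intronic_overlap Minimum intronic nucleotides an immature
#'   read must cover (RNA mode only).
#' @param seed Integer seed; fixed seed gives identical reads.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame: `read_id`, `class` (`genomic` / `mature` / `immature`),
#'   `start`, `strand`).
#' @export
simulate_reads <- function(template, depth, read_len, error_rate = 0,
                           mature_fraction = NULL,
                           min_intronic_overlap = 10L, seed = 1L) {
  stopifnot(depth > 0, error_rate >= 0, error_rate <= 0.05)
  set.seed(seed)
  rna <- inherits(template, "gene_structure")
  if (rna) {
    ## unspliced template is the pre-mRNA: first exon start to last exon end
    pre_a <- min(template$exons[, 1])
    pre_b <- max(template$exons[, 2])
    pre_mrna <- subseq0(template$locus_seq, pre_a, pre_b)
    ## pre-mRNA start positions whose read covers enough intronic sequence
    exonic_mask <- rep(FALSE, nchar(pre_mrna))
    for (i in seq_len(nrow(template$exons))) {
      exonic_mask[(template$exons[i, 1] - pre_a + 1L):
                    (template$exons[i, 2] - pre_a)] <- TRUE
    }
    intr_cum <- cumsum(!exonic_mask)
    ok <- if (read_len <= nchar(pre_mrna)) {
      starts <- 0:(nchar(pre_mrna) - read_len)
      starts[intr_cum[starts + read_len] -
               c(0L, intr_cum)[starts + 1L] >= min_intronic_overlap]
    } else integer()
  }
  base_len <- if (rna) nchar(template$locus_seq) else nchar(template)
  if (read_len > (if (rna) nchar(template$transcript) else base_len))
    stop("read_len exceeds template length")
  if (rna && length(ok) == 0L)
    stop("no pre-mRNA position yields the required intronic overlap")
  n_reads <- max(1L, ceiling(depth * base_len / read_len))
  add_errors <- function(s) {
    if (error_rate == 0) return(s)
    chars <- strsplit(s, "")[[1]]
    hits <- which(runif(length(chars)) < error_rate)
    for (h in hits) chars[h] <- sample(setdiff(c("A", "C", "G", "T"),
                                               chars[h]), 1L)
    paste0(chars, collapse = "")
  }
  reads <- character(n_reads)
  truth <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    if (rna) {
      mat <- runif(1) < mature_fraction
      tpl <- if (mat) template$transcript else pre_mrna
      klass <- if (mat) "mature" else "immature"
    } else {
      tpl <- template
      klass <- "genomic"
    }
    if (read_len > nchar(tpl)) {
      start <- 0L
      frag <- tpl
    } else if (rna && !mat) {
      start <- ok[sample.int(length(ok), 1L)]
      frag <- subseq0(tpl, start, start + read_len)
    } else {
      start <- sample.int(nchar(tpl) - read_len + 1L, 1L) - 1L
      frag <- subseq0(tpl, start, start + read_len)
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") frag <- revcomp(frag)
    reads[r] <- add_errors(frag)
    truth[[r]] <- data.frame(read_id = sprintf("read%05d", r),
                             class = klass, start = start, strand = strand,
                             stringsAsFactors = FALSE)
  }
  names(reads) <- sprintf("read%05d", seq_len(n_reads))
  list(reads = reads, truth = do.call(rbind, truth))
}

#' Write simulated reads as FASTQ
#'
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), reads[[i]], "+",
                 strrep("I", nchar(reads[[i]]))), con)
  }
  invisible(path)
}
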