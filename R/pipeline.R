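#' Annotate the coding status of a gene in every target species
#'
#' The core three-stage annotation: place every reference exon in each
#' species' orthologous locus, call ORF-disrupting lesions, and classify the
#' gene's coding status per species.
#'
#' @param model Reference `gene_model` (or a list of models for several
#'   genes).
#' @param loci Named list of [target_locus()] objects (one per species); for
#'   several genes, a list of such lists named by gene.
#' @param config A [vestige_config()].
#' @return List of class `annotation_run`: `statuses` (list of
#'   `gene_status`, named `species.gene`), `lesions` (pooled lesion data
#'   frame), `alignments` (per species.gene `exon_alignments`), `config`.
#' @export
run_annotate <- function(model, loci, config = vestige_config()) {
  if (inherits(model, "gene_model")) {
    models <- list(model)
    names(models) <- model$gene_id
    loci <- setNames(list(loci), model$gene_id)
  } else {
    models <- model
  }
  statuses <- list()
  alignments <- list()
  lesions <- empty_lesions()
  for (g in names(models)) {
    m <- models[[g]]
    for (sp in names(loci[[g]])) {
      locus <- loci[[g]][[sp]]
      key <- paste(sp, g, sep = ".")
      aln <- tryCatch(locate_exons(m, locus, config),
                      error = function(e)
                        stop("locate_exons failed for ", key, ": ",
                             conditionMessage(e), call. = FALSE))
      les <- tryCatch(call_lesions(aln, m, locus, config),
                      error = function(e)
                        stop("call_lesions failed for ", key, ": ",
                             conditionMessage(e), call. = FALSE))
      miss <- vapply(Filter(function(x) x$status == "missing", aln),
                     function(x) x$exon, 0L)
      gaps <- vapply(Filter(function(x) x$status == "gap_unresolved", aln),
                     function(x) x$exon, 0L)
      st <- classify_gene(les, missing_exons = miss, gap_exons = gaps,
                          model = m, config = config, species = sp)
      statuses[[key]] <- st
      alignments[[key]] <- aln
      lesions <- rbind(lesions, st$lesions)
    }
  }
  structure(list(statuses = statuses, alignments = alignments,
                 lesions = lesions, config = config),
            class = "annotation_run")
}

#' @export
print.annotation_run <- function(x, ...) {
  cat(sprintf("annotation run: %d species x gene pairs, %d lesion(s)\n",
              length(x$statuses), nrow(x$lesions)))
  for (s in x$statuses) print(s)
  invisible(x)
}

#' Match lesions across species and place shared losses on the tree
#'
#' Pools the lesions of an annotation run, groups identical signatures into
#' shared events, places each shared event on the species tree by Dollo
#' parsimony, and assembles the species-by-gene status matrix. Species with
#' unresolved assembly gaps for a gene are treated as missing data for that
#' gene's events.
#'
#' @param annotation An `annotation_run` from [run_annotate()].
#' @param tree `phylo` species tree containing every annotated species.
#' @return List of class `comparison_run`: `events` (signature table with
#'   `branch_label` and `conserved` for shared events), `placements`
#'   (per-event [assign_loss_branch()] results), `status_matrix`.
#' @export
run_compare <- function(annotation, tree) {
  statuses <- annotation$statuses
  species <- unique(vapply(statuses, function(s) s$species, ""))
  if (length(species) < 2L)
    stop("comparison needs at least two species")
  absent <- setdiff(species, tree$tip.label)
  if (length(absent))
    stop("species missing from tree: ", paste(absent, collapse = ", "))
  events <- match_shared_lesions(annotation$lesions)
  gap_species <- function(gene) {
    sp <- vapply(statuses, function(s)
      if (s$gene_id == gene && length(s$gap_exons)) s$species else "", "")
    sp[nzchar(sp)]
  }
  placements <- list()
  events$branch_label <- NA_character_
  events$conserved <- NA
  for (k in seq_len(nrow(events))) {
    if (!events$shared[k]) next
    carriers <- strsplit(events$carriers[k], ",")[[1]]
    pl <- assign_loss_branch(carriers, tree,
                             unassayable = gap_species(events$gene_id[k]))
    placements[[length(placements) + 1L]] <- c(list(event = k), pl)
    events$branch_label[k] <- pl$branch_label
    events$conserved[k] <- pl$conserved
  }
  structure(list(events = events, placements = placements,
                 status_matrix = build_status_matrix(statuses)),
            class = "comparison_run")
}

#' @export
print.comparison_run <- function(x, ...) {
  cat(sprintf("comparison run: %d signature(s), %d shared event(s)\n",
              nrow(x$events), sum(x$events$shared)))
  shared <- x$events[x$events$shared, , drop = FALSE]
  for (k in seq_len(nrow(shared))) {
    cat(sprintf("  %s %s @%d (%d carriers) -> %s%s\n",
                shared$gene_id[k], shared$type[k], shared$cds_coord[k],
                shared$n_carriers[k], shared$branch_label[k],
                if (isTRUE(shared$conserved[k])) " [conserved]" else ""))
  }
  invisible(x)
}

#' Validate called lesions against genomic read sets
#'
#' Runs [support_for_lesion()] for every lesion with a known locus
#' position, using the per-species read sets. Lesions whose locus context is
#' too short for the required flanks are reported with `validated = NA`.
#'
#' @param annotation An `annotation_run`.
#' @param loci Named list of [target_locus()] per species (single gene), or
#'   per gene a named list, matching [run_annotate()].
#' @param read_sets Named list: per species, a character vector of reads or
#'   a list of such vectors (independent read sets).
#' @param config A [vestige_config()].
#' @return Data frame: lesion key columns plus `n_support`, `n_contradict`,
#'   `n_readsets_supporting`, `validated`.
#' @export
run_validate <- function(annotation, loci, read_sets,
                         config = vestige_config()) {
  lesions <- annotation$lesions
  if (nrow(lesions) == 0L)
    return(cbind(empty_lesions()[0, ],
                 data.frame(n_support = integer(), n_contradict = integer(),
                            n_readsets_supporting = integer(),
                            validated = logical())))
  nested <- !inherits(loci[[1]], "target_locus")
  rows <- lapply(seq_len(nrow(lesions)), function(k) {
    l <- lesions[k, ]
    locus <- if (nested) loci[[l$gene_id]][[l$species]] else loci[[l$species]]
    reads <- read_sets[[l$species]]
    sup <- if (is.na(l$locus_pos) || is.null(reads)) {
      list(n_support = NA_integer_, n_contradict = NA_integer_,
           n_readsets_supporting = NA_integer_, validated = NA)
    } else {
      tryCatch(support_for_lesion(reads,
                                  list(seq = locus$seq, pos = l$locus_pos),
                                  l, config),
               error = function(e)
                 list(n_support = NA_integer_, n_contradict = NA_integer_,
                      n_readsets_supporting = NA_integer_, validated = NA))
    }
    cbind(l, data.frame(n_support = sup$n_support,
                        n_contradict = sup$n_contradict,
                        n_readsets_supporting = sup$n_readsets_supporting,
                        validated = sup$validated))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full inference pipeline and assemble a report
#'
#' Annotation, cross-species comparison and (when reads are supplied) read
#' validation, collected into a single report list that is fully
#' regenerable from the inputs and configuration.
#'
#' @param model Reference `gene_model` or list of models.
#' @param loci Per-species loci (see [run_annotate()]).
#' @param tree `phylo` species tree.
#' @param read_sets Optional per-species read sets (see [run_validate()]).
#' @param config A [vestige_config()].
#' @return List of class `run_report` with elements `config`, `statuses`,
#'   `lesions`, `events`, `status_matrix`, `read_support`.
#' @export
run_full <- function(model, loci, tree, read_sets = NULL,
                     config = vestige_config()) {
  ann <- run_annotate(model, loci, config)
  cmp <- run_compare(ann, tree)
  val <- if (!is.null(read_sets)) run_validate(ann, loci, read_sets, config)
  structure(list(config = unclass(config),
                 statuses = lapply(ann$statuses, function(s)
                   list(species = s$species, gene_id = s$gene_id,
                        verdict = s$verdict,
                        n_lesions = nrow(s$lesions),
                        missing_exons = s$missing_exons,
                        gap_exons = s$gap_exons)),
                 lesions = ann$lesions,
                 events = cmp$events,
                 status_matrix = cmp$status_matrix,
                 read_support = val),
            class = "run_report")
}

#' Write a run report to JSON
#'
#' @param report A `run_report` from [run_full()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  obj$status_matrix <- as.data.frame(obj$status_matrix) |>
    (\(d) cbind(species = rownames(d), d))()
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
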