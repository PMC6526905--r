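lesion_signature <- function(lesions) {
  paste(lesions$gene_id, lesions$type, lesions$cds_coord, lesions$length,
        lesions$alt_allele, sep = "|")
}

#' Group identical lesions across species into shared events
#'
#' Lesions are matched by exact signature equality — gene, type,
#' left-normalized CDS coordinate, length and alternate allele — so that the
#' same founding mutation inherited by several species forms one event.
#' Premature stops that are consequences of an upstream frameshift are
#' excluded from matching (the frameshift itself is the heritable
#' signature). Singleton groups are not events but are retained in the
#' returned table with `n_carriers = 1` for convergence reporting.
#'
#' @param lesions Lesion data frame pooled over species (normalized, in
#'   reference CDS coordinates).
#' @param min_carriers Minimum carrier count for a shared event (default 2).
#' @return Data frame with one row per signature: `gene_id`, `type`,
#'   `cds_coord`, `length`, `alt_allele`, `n_carriers`, `carriers`
#'   (comma-separated species) and `shared` (logical).
#' @export
match_shared_lesions <- function(lesions, min_carriers = 2L) {
  empty <- data.frame(gene_id = character(), type = character(),
                      cds_coord = integer(), length = integer(),
                      alt_allele = character(), n_carriers = integer(),
                      carriers = character(), shared = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(lesions) == 0L) return(empty)
  les <- lesions[!(lesions$type == "premature_stop" & lesions$consequence), ,
                 drop = FALSE]
  if (nrow(les) == 0L) return(empty)
  sig <- lesion_signature(les)
  groups <- split(seq_len(nrow(les)), sig)
  rows <- lapply(groups, function(idx) {
    sp <- sort(unique(les$species[idx]))
    first <- les[idx[1L], ]
    data.frame(gene_id = first$gene_id, type = first$type,
               cds_coord = first$cds_coord, length = first$length,
               alt_allele = first$alt_allele,
               n_carriers = length(sp),
               carriers = paste(sp, collapse = ","),
               shared = length(sp) >= min_carriers,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$cds_coord, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place a shared lesion on the species tree by Dollo parsimony
#'
#' Under Dollo parsimony an inactivating lesion arises once and is never
#' regained, so a lesion shared by a set of species is placed on the branch
#' directly above their most recent common ancestor. Species with unresolved
#' assembly gaps at the lesion locus can be passed as `unassayable`: they are
#' excluded from both the carrier and non-carrier sets (missing data). The
#' event is `conserved` when every assayable leaf below the assigned branch
#' carries the lesion.
#'
#' @param carriers Character vector of carrier species (tree leaves).
#' @param tree `phylo` species tree.
#' @param unassayable Species with no data at this locus.
#' @return List with `mrca` (node id), `branch` (length-2 integer vector
#'   `c(parent, child)`; parent is NA when the carriers span the root),
#'   `branch_label` (e.g. `"stem of (A,B)"`), `carriers`, `conserved`.
#' @export
assign_loss_branch <- function(carriers, tree, unassayable = character()) {
  if (length(carriers) == 0L) stop("carrier set is empty")
  if (!all(carriers %in% tree$tip.label))
    stop("carrier(s) not in tree: ",
         paste(setdiff(carriers, tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  if (length(carriers) == 1L) {
    node <- match(carriers, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, carriers)
  }
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) == 0L) parent <- NA_integer_
  clade_tips <- if (node <= ntip) tree$tip.label[node] else
    ape::extract.clade(tree, node)$tip.label
  assayable <- setdiff(clade_tips, unassayable)
  conserved <- length(assayable) > 0L && all(assayable %in% carriers)
  label <- if (node <= ntip) {
    paste0("terminal branch of ", tree$tip.label[node])
  } else if (is.na(parent)) {
    "root stem"
  } else {
    paste0("stem of (", paste(sort(clade_tips), collapse = ","), ")")
  }
  list(mrca = node, branch = c(parent = parent, child = node),
       branch_label = label, carriers = sort(carriers),
       conserved = conserved)
}

#' Compare flanking-gene order between target and reference loci
#'
#' Orthology support by synteny: counts the flanking genes shared between
#' the two loci and checks whether the shared genes occur in the same order
#' in both (or fully reversed, since assembly strand is arbitrary).
#'
#' @param target_flanks,reference_flanks Character vectors of gene symbols
#'   ordered 5' to 3' along each locus.
#' @return List with `shared` (count) and `order_conserved` (logical).
#' @examples
#' check_synteny(c("Pmp2", "Fabp9", "Fabp4"), c("Pmp2", "Fabp9", "Fabp4"))
#' @export
check_synteny <- function(target_flanks, reference_flanks) {
  stopifnot(length(target_flanks) > 0L, length(reference_flanks) > 0L)
  common <- intersect(target_flanks, reference_flanks)
  if (length(common) == 0L)
    return(list(shared = 0L, order_conserved = FALSE))
  t_ord <- target_flanks[target_flanks %in% common]
  r_ord <- reference_flanks[reference_flanks %in% common]
  conserved <- identical(t_ord, r_ord) || identical(t_ord, rev(r_ord))
  list(shared = length(common), order_conserved = conserved)
}

#' Assemble per-species gene verdicts into a status matrix
#'
#' @param statuses List of `gene_status` objects (at most one per
#'   species-gene pair).
#' @return Character matrix, rows = species, columns = genes, cells =
#'   verdicts, with `"not_assayed"` for absent pairs.
#' @export
build_status_matrix <- function(statuses) {
  sp <- vapply(statuses, function(s) s$species, "")
  gn <- vapply(statuses, function(s) s$gene_id, "")
  if (anyDuplicated(paste(sp, gn)))
    stop("duplicate species x gene status: ",
         paste(unique(paste(sp, gn)[duplicated(paste(sp, gn))]),
               collapse = "; "))
  species <- sort(unique(sp))
  genes <- sort(unique(gn))
  m <- matrix("not_assayed", length(species), length(genes),
              dimnames = list(species, genes))
  for (s in statuses) m[s$species, s$gene_id] <- s$verdict
  m
}

#' Write a status matrix to TSV
#' @param matrix Character matrix from [build_status_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_status_matrix <- function(matrix, path) {
  df <- data.frame(species = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a status matrix written by [write_status_matrix()]
#' @param path TSV path.
#' @return Character matrix with species rownames.
#' @export
read_status_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$species
  m
}
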