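#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   DNAString reverseComplement pairwiseAlignment score pattern subject
#' @importFrom IRanges IRanges
#' @importFrom stats rbinom runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

## 0-based half-open substring; all genomic/CDS coordinates in the package
## use this convention (labelled "0-based half-open" in every report header).
subseq0 <- function(s, start, end) substr(s, start + 1L, end)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; IUPAC ambiguity letters are preserved; record
#' order is retained. An empty file yields an empty vector.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of DNA sequences.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgtn"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(setNames(character(), character()))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      ## locate the first offending line so the message is actionable
      lines <- readLines(path, warn = FALSE)
      bad <- which(!grepl("^(>|[ACGTUKMRSWBDHVNacgtukmrswbdhvn.-]*$)", lines))
      where <- if (length(bad)) paste0(" (line ", bad[1L], ")") else ""
      stop("malformed FASTA in ", path, where, ": ", conditionMessage(e),
           call. = FALSE)
    })
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

new_gene_model <- function(gene_id, species, genomic_seq, exons,
                           critical_intervals = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene model needs at least one exon")
  if (any(exons[, 2] <= exons[, 1]))
    stop("exon intervals must be non-empty (0-based half-open)")
  if (nrow(exons) > 1L && any(diff(exons[, 1]) <= 0 |
                              exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("exons must be non-overlapping and strictly increasing")
  if (max(exons[, 2]) > nchar(genomic_seq))
    stop("exon coordinates exceed genomic sequence bounds")
  lens <- exons[, 2] - exons[, 1]
  phases <- (cumsum(c(0L, lens[-length(lens)]))) %% 3L
  cds <- paste0(vapply(seq_len(nrow(exons)), function(i)
    subseq0(genomic_seq, exons[i, 1], exons[i, 2]), ""), collapse = "")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length (", nchar(cds), ") of ", gene_id,
         " is not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  if (!codons[length(codons)] %in% STOP_CODONS)
    stop("CDS of ", gene_id, " does not end in a stop codon")
  internal <- which(codons[-length(codons)] %in% STOP_CODONS)
  if (length(internal))
    stop("CDS of ", gene_id, " contains an internal stop codon at codon ",
         internal[1L])
  structure(list(gene_id = gene_id, species = species,
                 genomic_seq = toupper(genomic_seq),
                 exons = exons, phases = as.integer(phases),
                 cds_seq = cds,
                 stop_coord = nchar(cds) - 3L,
                 critical_intervals = critical_intervals),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene model '%s' (%s): %d exons, CDS %d nt, locus %d nt\n",
              x$gene_id, x$species, nrow(x$exons), nchar(x$cds_seq),
              nchar(x$genomic_seq)))
  invisible(x)
}

#' Exon lengths of a gene model
#' @param model A `gene_model`.
#' @return Integer vector of exon lengths (nt).
#' @export
exon_lengths <- function(model) model$exons[, 2] - model$exons[, 1]

## 0-based CDS offset of the first base of each exon
cds_offsets <- function(model) {
  lens <- exon_lengths(model)
  cumsum(c(0L, lens[-length(lens)]))
}

#' Build a reference gene model from GFF3 + FASTA
#'
#' Collects the CDS features of `gene_id` (matched against the features'
#' `Parent`, `ID` or `gene_id` attribute), extracts the coding exons from the
#' genomic sequence and normalizes minus-strand genes to the plus strand, so
#' downstream stages never see strand. Only CDS features are used; UTR exons
#' are ignored because the analysis concerns the open reading frame.
#'
#' @param gff3_path GFF3 annotation file.
#' @param fasta_path Genomic FASTA containing the annotated sequence.
#' @param gene_id Identifier of the gene to build.
#' @param species Species label stored in the model.
#' @param critical_intervals Optional list of 0-based half-open CDS intervals
#'   encoding known functional motifs (e.g. an enzyme active site); a
#'   premature stop upstream of any of these is always rated strong.
#' @return A `gene_model` (plus-strand; invariants checked).
#' @export
build_gene_model <- function(gff3_path, fasta_path, gene_id,
                             species = "reference",
                             critical_intervals = NULL) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gff)
  pick <- function(col) {
    if (!col %in% names(md)) return(rep(FALSE, length(gff)))
    v <- md[[col]]
    if (methods::is(v, "List") || is.list(v)) {
      vapply(v, function(x) gene_id %in% x, logical(1))
    } else !is.na(v) & v == gene_id
  }
  sel <- md$type == "CDS" & (pick("Parent") | pick("ID") | pick("gene_id"))
  cds <- gff[sel]
  if (length(cds) == 0L)
    stop("no CDS features found for gene '", gene_id, "' in ", gff3_path)
  strand <- as.character(BiocGenerics::strand(cds))
  if (length(unique(strand)) != 1L)
    stop("CDS features of '", gene_id, "' are on mixed strands")
  seqname <- as.character(GenomeInfoDb::seqnames(cds))[1L]
  seqs <- read_fasta(fasta_path)
  if (!seqname %in% names(seqs))
    stop("sequence '", seqname, "' not found in ", fasta_path)
  genome <- seqs[[seqname]]
  ## GFF3 is 1-based closed; convert to 0-based half-open
  starts <- BiocGenerics::start(cds) - 1L
  ends <- BiocGenerics::end(cds)
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  if (max(ends) > nchar(genome))
    stop("CDS coordinates of '", gene_id, "' exceed sequence bounds")
  if (strand[1L] == "-") {
    L <- nchar(genome)
    genome <- revcomp(genome)
    new_starts <- L - rev(ends)
    new_ends <- L - rev(starts)
    starts <- new_starts; ends <- new_ends
  }
  new_gene_model(gene_id, species, genome, cbind(starts, ends),
                 critical_intervals = critical_intervals)
}

#' Read a rooted species tree from a newick file
#'
#' @param path Newick file with unique leaf labels.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  np <- nchar(gsub("[^(]", "", txt)) - nchar(gsub("[^)]", "", txt))
  if (np != 0L) stop("unbalanced parentheses in newick file ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error in ", path,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("newick parse error in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels in species tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' An empty lesion table
#'
#' Lesion tables are plain data frames with one row per inactivating
#' mutation; every lesion-producing function in the package returns this
#' shape. Exon and intron indices are 1-based; `cds_coord` is a 0-based
#' position in the reference CDS frame.
#'
#' @return A zero-row lesion data frame with the canonical columns.
#' @export
empty_lesions <- function() {
  data.frame(species = character(), gene_id = character(),
             type = character(), exon = integer(), intron = integer(),
             cds_coord = integer(), length = integer(),
             ref_allele = character(), alt_allele = character(),
             frameshift = logical(), severity = character(),
             consequence = logical(), locus_pos = integer(),
             stringsAsFactors = FALSE)
}

LESION_TYPES <- c("insertion", "deletion", "premature_stop",
                  "splice_donor", "splice_acceptor", "exon_deletion")

validate_lesions <- function(lesions) {
  stopifnot(is.data.frame(lesions))
  missing_cols <- setdiff(names(empty_lesions()), names(lesions))
  if (length(missing_cols))
    stop("lesion table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(lesions) == 0L) return(invisible(lesions))
  if (!all(lesions$type %in% LESION_TYPES))
    stop("unknown lesion type(s): ",
         paste(setdiff(lesions$type, LESION_TYPES), collapse = ", "))
  indel <- lesions$type %in% c("insertion", "deletion")
  want_fs <- indel & (lesions$length %% 3L != 0L)
  if (!identical(as.logical(lesions$frameshift), as.logical(want_fs)))
    stop("frameshift flag inconsistent with lesion type/length")
  splice <- lesions$type %in% c("splice_donor", "splice_acceptor")
  if (any(nchar(lesions$ref_allele[splice]) != 2L |
          nchar(lesions$alt_allele[splice]) != 2L))
    stop("splice lesions must carry 2-nt alleles")
  invisible(lesions)
}

#' Write a lesion table to TSV
#'
#' One row per lesion, ordered deterministically by (species, gene,
#' CDS coordinate, type). Exon/intron indices are 1-based; `cds_coord` is
#' 0-based in the reference CDS frame, as stated in the header comment line.
#'
#' @param lesions Lesion data frame (see [empty_lesions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(lesions, path) {
  validate_lesions(lesions)
  cols <- names(empty_lesions())
  tab <- lesions[do.call(order, lesions[c("species", "gene_id",
                                          "cds_coord", "type")]), cols,
                 drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vestige lesion table; exon/intron 1-based; cds_coord 0-based in reference CDS frame",
             con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lesion table written by [write_lesion_table()]
#'
#' @param path TSV path.
#' @return Lesion data frame.
#' @export
read_lesion_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(species = "character",
                                   gene_id = "character",
                                   type = "character",
                                   ref_allele = "character",
                                   alt_allele = "character"))
  if (nrow(tab) == 0L) return(empty_lesions())
  tab$exon <- as.integer(tab$exon)
  tab$intron <- as.integer(tab$intron)
  tab$cds_coord <- as.integer(tab$cds_coord)
  tab$length <- as.integer(tab$length)
  tab$frameshift <- as.logical(tab$frameshift)
  tab$severity <- as.character(tab$severity)
  tab$consequence <- as.logical(tab$consequence)
  tab$locus_pos <- as.integer(tab$locus_pos)
  tab$ref_allele[is.na(tab$ref_allele)] <- ""
  tab$alt_allele[is.na(tab$alt_allele)] <- ""
  validate_lesions(tab)
  tab
}

#' Construct a target locus
#'
#' @param species Species label.
#' @param seq Genomic sequence of the orthologous locus (IUPAC; may contain
#'   N runs from assembly gaps).
#' @param locus_id Locus identifier.
#' @param flanking_genes Optional character vector of flanking gene symbols,
#'   ordered 5' to 3', used for synteny checks.
#' @return A `target_locus` object.
#' @export
target_locus <- function(species, seq, locus_id = species,
                         flanking_genes = NULL) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("target locus sequence is empty")
  structure(list(species = species, locus_id = locus_id, seq = seq,
                 flanking_genes = flanking_genes),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  cat(sprintf("target locus '%s' (%s): %d nt\n", x$locus_id, x$species,
              nchar(x$seq)))
  invisible(x)
}
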