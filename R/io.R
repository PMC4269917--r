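# Readers and writers for the plain-text formats the pipeline consumes and
# emits: expression/metadata TSV, edge lists, GMT gene sets, FASTA promoters.

#' Write / read a gene x sample expression matrix as TSV
#'
#' First column `gene`, remaining columns one per sample id.
#' @param mat Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_expression_tsv` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  if (anyNA(mat))
    stop("missing values in expression matrix (imputation is not a default)")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  mat
}

#' Write / read a sample metadata table as TSV
#' @param metadata data.frame with at least `sample_id`, `subject_id`,
#'   `tissue`, `sex`.
#' @param path File path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_tsv
#' @export
read_metadata_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a TF x gene (or TF x TF) matrix as a weighted edge list
#'
#' Three tab-separated columns: source, target, weight. `read_edge_list`
#' reconstructs the dense matrix; absent pairs are 0.
#'
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @param nonzero_only Drop zero-weight edges on write (default TRUE).
#' @param rows,cols Optional id universes for reading (default: ids seen).
#' @export
write_edge_list <- function(mat, path, nonzero_only = TRUE) {
  idx <- if (nonzero_only) which(mat != 0, arr.ind = TRUE) else
    as.matrix(expand.grid(row = seq_len(nrow(mat)), col = seq_len(ncol(mat))))
  df <- data.frame(source = rownames(mat)[idx[, 1]],
                   target = colnames(mat)[idx[, 2]],
                   weight = mat[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, rows = NULL, cols = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rows <- rows %||% sort(unique(df[[1]]))
  cols <- cols %||% sort(unique(df[[2]]))
  mat <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  mat[cbind(match(df[[1]], rows), match(df[[2]], cols))] <- df[[3]]
  mat
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member ids.
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write / read promoter FASTA
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path File path.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read transcription start sites from BED
#'
#' BED is 0-based half-open; the TSS is `start` for plus-strand records and
#' `end - 1` for minus-strand ones. Returns 1-based coordinates.
#'
#' @param path BED file (chrom, start, end, name, \[score, strand\]).
#' @return data.frame: `gene`, `chrom`, `tss_pos` (1-based), `strand`.
#' @export
read_tss_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  strand <- if (ncol(df) >= 6) df[[6]] else "+"
  tss0 <- ifelse(strand == "-", df[[3]] - 1L, df[[2]])
  data.frame(gene = df[[4]], chrom = df[[1]], tss_pos = tss0 + 1L,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits `expression_<tissue>.tsv` per tissue plus `metadata.tsv`.
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ti in names(cohort$expression))
    write_expression_tsv(cohort$expression[[ti]],
                         file.path(dir, paste0("expression_", ti, ".tsv")))
  write_metadata_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Write synthetic regulatory truth to a directory
#'
#' Emits `motif_prior.tsv` and `ppi.tsv` edge lists plus `gene_sets.gmt`.
#' @param truth A [generate_regulatory_truth()] result.
#' @param dir Output directory.
#' @export
write_regulatory_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(truth$motif_prior, file.path(dir, "motif_prior.tsv"))
  write_edge_list(truth$ppi, file.path(dir, "ppi.tsv"))
  write_gmt(truth$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
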