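# Count-matrix I/O (TSV / CSV / MatrixMarket triplet) and low-count
# filtering. TSV is canonical: genes in rows (first column = gene ids),
# samples in columns (header = sample ids).

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tsv" = "tsv", "txt" = "tsv", "tab" = "tsv",
    "csv" = "csv",
    "mtx" = "mtx",
    stop("cannot infer format from extension '.", ext,
         "'; pass format = \"tsv\", \"csv\" or \"mtx\"")
  )
}

read_id_file <- function(path, what) {
  if (is.null(path)) stop("MatrixMarket input needs a ", what, " id file")
  if (!file.exists(path)) stop(what, " id file not found: ", path)
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Read a genes-by-samples count matrix
#'
#' Delimited input must have a header row of sample ids and gene ids in the
#' first column. MatrixMarket (`format = "mtx"`) input is a sparse triplet
#' file plus two plain-text id files, one id per line.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; inferred from the extension
#'   when `NULL`.
#' @param gene_ids_file,sample_ids_file id files for MatrixMarket input.
#' @return validated count matrix (see [as_count_matrix()]).
#' @export
read_counts <- function(path, format = NULL, gene_ids_file = NULL,
                        sample_ids_file = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(format)) format <- infer_format(path)
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    genes <- read_id_file(gene_ids_file, "gene")
    samples <- read_id_file(sample_ids_file, "sample")
    return(as_count_matrix(m, gene_ids = genes, sample_ids = samples,
                           require_samples = 1L))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene-id column plus >= 1 sample")
  genes <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric count at gene '%s', sample '%s': '%s'",
                 genes[bad[1L, 1L]], colnames(body)[bad[1L, 2L]],
                 body[bad[1L, 1L], bad[1L, 2L]]))
  }
  as_count_matrix(num, gene_ids = genes, sample_ids = colnames(body),
                  require_samples = 1L)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; `read -> write -> read` is the identity on
#' valid matrices. For MatrixMarket output the two id files are written
#' next to the matrix as `<path>.genes` and `<path>.samples` unless given.
#'
#' @param counts count matrix.
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; inferred when `NULL`.
#' @param gene_ids_file,sample_ids_file id file paths for `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = NULL, gene_ids_file = NULL,
                         sample_ids_file = NULL) {
  counts <- as_count_matrix(counts, require_samples = 1L)
  if (is.null(format)) format <- infer_format(path)
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    if (is.null(gene_ids_file)) gene_ids_file <- paste0(path, ".genes")
    if (is.null(sample_ids_file)) sample_ids_file <- paste0(path, ".samples")
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), gene_ids_file)
    writeLines(colnames(counts), sample_ids_file)
    return(invisible(path))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove genes with uniformly low counts
#'
#' Keeps genes with a count of at least `min_count` in at least
#' `min_samples` samples — a transparent stand-in for design-aware
#' expression filters. Gene order and the sample set are preserved.
#'
#' @param counts count matrix.
#' @param min_count minimum count (default 10).
#' @param min_samples minimum number of samples reaching it (default 2).
#' @return filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 10L, min_samples = 2L) {
  counts <- as_count_matrix(counts, require_samples = 1L)
  keep <- rowSums(counts >= min_count) >= min_samples
  if (!any(keep)) stop("low-count filter removed every gene")
  counts[keep, , drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write normalization results as TSV tables
#'
#' Produces `<prefix>factors.tsv` (sample_id, scale_factor,
#' effective_library_size) and `<prefix>alphas.tsv` (reference_id,
#' sample_id, alpha_M, alpha_A).
#'
#' @param result an [atmm_normalize()] result.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_normalization <- function(result, prefix) {
  stopifnot(inherits(result, "atmm_norm"))
  f_path <- paste0(prefix, "factors.tsv")
  a_path <- paste0(prefix, "alphas.tsv")
  write_tsv(data.frame(
    sample_id = names(result$factors),
    scale_factor = unname(result$factors),
    effective_library_size = unname(result$effective_library_sizes),
    stringsAsFactors = FALSE
  ), f_path)
  write_tsv(result$alpha_table, a_path)
  invisible(c(f_path, a_path))
}
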