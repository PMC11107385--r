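#' Validate and coerce a genes-by-samples count matrix
#'
#' Normalization in this package operates on plain numeric matrices with
#' genes in rows and samples in columns. `as_count_matrix()` checks the
#' invariants every downstream function relies on: non-negative integral
#' entries, unique gene and sample identifiers, and (for normalization) at
#' least two samples.
#'
#' @param x matrix or data.frame of read counts, genes in rows, samples in
#'   columns. A data.frame is coerced with `as.matrix()`.
#' @param gene_ids optional character vector of row identifiers; defaults to
#'   existing rownames or `gene_1..gene_g`.
#' @param sample_ids optional character vector of column identifiers;
#'   defaults to existing colnames or `sample_1..sample_n`.
#' @param require_samples minimum number of columns (2 for normalization).
#' @return a base numeric matrix with validated dimnames.
#' @examples
#' m <- as_count_matrix(matrix(c(1, 2, 3, 4), 2, 2))
#' library_sizes(m)
#' @export
as_count_matrix <- function(x, gene_ids = NULL, sample_ids = NULL,
                            require_samples = 2L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("counts must be a numeric matrix (genes x samples)")
  }
  if (nrow(x) < 1L) stop("count matrix must contain at least one gene")
  if (ncol(x) < require_samples) {
    stop("count matrix must contain at least ", require_samples, " samples")
  }
  bad <- which(!is.finite(x) | x < 0 | x != floor(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "counts must be non-negative integers; offending cell: row %d, column %d (value %s)",
      bad[1L, 1L], bad[1L, 2L], format(x[bad[1L, , drop = FALSE]])
    ))
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(x)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(x)))
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(x)
    if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(x)))
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(x)) stop("gene_ids length does not match row count")
  if (length(sample_ids) != ncol(x)) stop("sample_ids length does not match column count")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ", sample_ids[duplicated(sample_ids)][1L])
  }
  dimnames(x) <- list(gene_ids, sample_ids)
  storage.mode(x) <- "double"
  x
}

#' Library sizes (total raw read counts per sample)
#'
#' @param counts validated count matrix (see [as_count_matrix()]).
#' @return numeric vector of positive column sums, named by sample.
#' @details A sample whose counts sum to zero has no defined proportions
#'   \eqn{Y_{gk}/N_k}, so an all-zero column is an error, not a zero.
#' @export
library_sizes <- function(counts) {
  counts <- as_count_matrix(counts, require_samples = 1L)
  n <- colSums(counts)
  if (any(n == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[n == 0], collapse = ", "))
  }
  n
}
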