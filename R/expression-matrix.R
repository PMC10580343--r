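#' Bundle a count matrix with per-cell metadata
#'
#' The central container for single-cell counts: a sparse cells x genes
#' integer matrix plus a cell-metadata tibble aligned row-for-row with the
#' matrix. Metadata carries at least `cell_id`; typical columns are `sample`,
#' `patient`, `pathology_group` (one of `"normal"`, `"AIS/MIA"`, `"IAC"`) and
#' `cell_type`.
#'
#' @param counts Matrix-like cells x genes non-negative counts with unique
#'   row (cell) and column (gene) names. Coerced to `Matrix::dgCMatrix`.
#' @param cell_meta Data frame with a `cell_id` column matching the matrix
#'   row names (any order; it is re-aligned). If `NULL`, a minimal metadata
#'   table is created.
#' @return An object of class `mplc_matrix`: a list with elements `counts`
#'   (dgCMatrix) and `cell_meta` (tibble).
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' em <- expression_matrix(m)
#' dim(em)
#' @export
expression_matrix <- function(counts, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have cell (row) and gene (column) names.")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("Cell and gene identifiers must be unique.")
  }
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) abort("Counts must be non-negative.")
  if (is.null(cell_meta)) {
    cell_meta <- tibble(cell_id = rownames(counts))
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) abort("`cell_meta` needs a `cell_id` column.")
    if (!setequal(cell_meta$cell_id, rownames(counts)) ||
        nrow(cell_meta) != nrow(counts)) {
      abort("`cell_meta$cell_id` must match the matrix rows exactly (1:1).")
    }
    cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), ]
  }
  structure(list(counts = counts, cell_meta = cell_meta), class = "mplc_matrix")
}

#' @export
dim.mplc_matrix <- function(x) dim(x$counts)

#' @export
dimnames.mplc_matrix <- function(x) dimnames(x$counts)

#' @export
print.mplc_matrix <- function(x, ...) {
  cat(sprintf("<mplc_matrix> %d cells x %d genes (%.1f%% non-zero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  meta_cols <- setdiff(names(x$cell_meta), "cell_id")
  if (length(meta_cols)) cat("cell_meta:", paste(meta_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix by cells and/or genes
#'
#' @param x An `mplc_matrix`.
#' @param cells,genes Character vectors of identifiers, or logical/integer
#'   indices; `NULL` keeps everything.
#' @param ... Unused.
#' @return A new `mplc_matrix`.
#' @export
subset.mplc_matrix <- function(x, cells = NULL, genes = NULL, ...) {
  cells <- cells %||% seq_len(nrow(x$counts))
  genes <- genes %||% seq_len(ncol(x$counts))
  counts <- x$counts[cells, genes, drop = FALSE]
  meta <- x$cell_meta[match(rownames(counts), x$cell_meta$cell_id), ]
  expression_matrix(counts, meta)
}

#' Library-size normalised log2 expression
#'
#' Counts-per-`scale_factor` (default counts per 10k) followed by
#' `log2(x + 1)`. This is the working scale for copy-number inference and
#' interaction scoring.
#'
#' @param x An `mplc_matrix` or a base/sparse matrix of counts (cells x genes).
#' @param scale_factor Target library size, default `1e4`.
#' @return A dense numeric matrix, cells x genes.
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "mplc_matrix")) x$counts else x
  libs <- Matrix::rowSums(counts)
  libs[libs == 0] <- 1   # all-zero cells stay all-zero
  m <- as.matrix(counts / libs * scale_factor)
  log2(m + 1)
}
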