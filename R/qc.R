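#' Per-cell quality-control report
#'
#' Flags low-quality cells with the conventional droplet filters: fewer than
#' `min_umi` total UMIs, more than `max_mito` of UMIs from mitochondrial
#' genes, or a detected-gene count outside `(min_genes, max_genes)`.
#' Boundary semantics are strict: a cell with exactly 500 UMIs, exactly 200
#' or 5000 detected genes, or exactly 25% mitochondrial UMIs passes. A gene
#' is "detected" when its count is >= 1.
#'
#' @param x An [expression_matrix()] (or bare counts matrix, cells x genes).
#' @param mito_gene_prefix Prefix identifying mitochondrial genes
#'   (default `"MT-"`). If no gene matches, a warning is emitted and the
#'   mitochondrial fraction is 0 for every cell.
#' @param min_umi,max_mito,min_genes,max_genes Thresholds; a cell fails iff
#'   `total_umi < min_umi` OR `mito_fraction > max_mito` OR
#'   `n_genes_detected > max_genes` OR `n_genes_detected < min_genes`.
#' @return A tibble of class `mplc_qc` with one row per cell: `cell_id`,
#'   `total_umi`, `n_genes_detected`, `mito_fraction`, `pass`, and
#'   `failure_reasons` (comma-separated; `""` when the cell passes). The
#'   thresholds used are attached as the `thresholds` attribute.
#' @examples
#' cfg <- simulation_config(n_ref_cells = 30, n_tumor_cells = 0,
#'                          n_genes = 100, n_chromosomes = 2, seed = 5)
#' qc <- compute_cell_qc(simulate_counts(cfg)$matrix)
#' table(qc$pass)
#' @export
compute_cell_qc <- function(x, mito_gene_prefix = "MT-",
                            min_umi = 500, max_mito = 0.25,
                            min_genes = 200, max_genes = 5000) {
  counts <- if (inherits(x, "mplc_matrix")) x$counts else x
  if (nrow(counts) == 0 || ncol(counts) == 0) abort("Empty expression matrix.")
  total <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts >= 1)
  mito_idx <- startsWith(colnames(counts), mito_gene_prefix)
  if (!any(mito_idx)) {
    warn(sprintf("No gene matches mito prefix '%s'; mito_fraction set to 0.",
                 mito_gene_prefix))
    mito_frac <- rep(0, nrow(counts))
  } else {
    mito <- Matrix::rowSums(counts[, mito_idx, drop = FALSE])
    mito_frac <- ifelse(total > 0, mito / total, 0)
  }
  reasons <- mapply(function(u, m, g) {
    r <- character(0)
    if (u < min_umi) r <- c(r, "low_umi")
    if (m > max_mito) r <- c(r, "high_mito")
    if (g > max_genes) r <- c(r, "high_genes")
    if (g < min_genes) r <- c(r, "low_genes")
    paste(r, collapse = ",")
  }, total, mito_frac, ngene, USE.NAMES = FALSE)
  out <- tibble(
    cell_id = rownames(counts),
    total_umi = as.numeric(total),
    n_genes_detected = as.integer(ngene),
    mito_fraction = as.numeric(mito_frac),
    pass = reasons == "",
    failure_reasons = reasons
  )
  attr(out, "thresholds") <- list(min_umi = min_umi, max_mito = max_mito,
                                  min_genes = min_genes, max_genes = max_genes,
                                  mito_gene_prefix = mito_gene_prefix)
  class(out) <- c("mplc_qc", class(out))
  out
}

#' Drop cells that fail quality control
#'
#' @param x An [expression_matrix()].
#' @param qc Optional precomputed [compute_cell_qc()] report; computed with
#'   defaults (plus `...`) when missing.
#' @param ... Passed to [compute_cell_qc()] when `qc` is `NULL`.
#' @return An [expression_matrix()] restricted to passing cells.
#' @export
filter_cells <- function(x, qc = NULL, ...) {
  qc <- qc %||% compute_cell_qc(x, ...)
  keep <- qc$cell_id[qc$pass]
  if (!length(keep)) abort("Quality control removed every cell.")
  subset(x, cells = keep)
}

#' Remove genes expressed in too few cells
#'
#' Keeps genes whose expressing-cell fraction (cells with count >= 1) is
#' strictly greater than `min_expressing_fraction`; gene order is otherwise
#' preserved. With the default 0.001, a gene seen in exactly 0.1% of cells
#' is removed.
#'
#' @param x An [expression_matrix()].
#' @param min_expressing_fraction Strict lower bound on the expressing
#'   fraction, default `0.001`.
#' @return A filtered [expression_matrix()].
#' @export
filter_genes <- function(x, min_expressing_fraction = 0.001) {
  stopifnot(inherits(x, "mplc_matrix"))
  assert_scalar_number(min_expressing_fraction, "min_expressing_fraction", 0, 1)
  frac <- Matrix::colSums(x$counts >= 1) / nrow(x$counts)
  keep <- which(frac > min_expressing_fraction)
  if (!length(keep)) abort("Gene filter removed every gene.")
  subset(x, genes = keep)
}

#' Select highly variable genes by standardized dispersion
#'
#' The classic mean-binned dispersion recipe: per-gene log dispersion
#' (variance/mean) of library-size-normalised counts is z-scored within
#' bins of similar mean expression, and the top `n_features` genes by that
#' standardized dispersion are returned. Ties break deterministically by
#' raw dispersion and then by gene id (relevant for degenerate inputs where
#' whole bins share one dispersion value).
#'
#' @param x An [expression_matrix()].
#' @param n_features Number of genes to select (default 2000); must not
#'   exceed the gene count.
#' @param n_bins Number of equal-frequency mean-expression bins (default 20).
#' @return Character vector of `n_features` gene ids, ranked most variable
#'   first.
#' @export
select_hvg <- function(x, n_features = 2000, n_bins = 20) {
  stopifnot(inherits(x, "mplc_matrix"))
  n_features <- assert_count(n_features, "n_features")
  if (n_features > ncol(x$counts)) {
    abort(sprintf("`n_features` (%d) exceeds the gene count (%d).",
                  n_features, ncol(x$counts)))
  }
  libs <- Matrix::rowSums(x$counts)
  libs[libs == 0] <- 1
  norm <- x$counts / libs * 1e4
  mu <- Matrix::colMeans(norm)
  # E[x^2] - mu^2, with the n/(n-1) correction
  ex2 <- Matrix::colMeans(norm^2)
  n <- nrow(norm)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  log_disp <- log1p(disp)
  bins <- cut(mu, breaks = unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  std <- stats::ave(log_disp, bins, FUN = function(z) {
    s <- sd(z)
    if (!is.finite(s) || s == 0) rep(0, length(z)) else (z - mean(z)) / s
  })
  ids <- colnames(x$counts)
  ord <- order(-std, -log_disp, ids)
  ids[ord][seq_len(n_features)]
}

#' @method tidy mplc_qc
#' @export
tidy.mplc_qc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mplc_qc")
  attr(out, "thresholds") <- NULL
  out
}

#' @method glance mplc_qc
#' @export
glance.mplc_qc <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_pass = sum(x$pass),
    fraction_pass = mean(x$pass),
    median_umi = median(x$total_umi),
    median_genes = median(x$n_genes_detected),
    median_mito = median(x$mito_fraction)
  )
}
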