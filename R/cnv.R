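#' Infer genome-ordered relative copy-number profiles from expression
#'
#' Expression-based CNV inference in the style long used for tumour
#' scRNA-seq: genes are placed in genomic order, each cell's log expression
#' is contrasted with the mean of a normal (reference) cell set, extreme
#' residuals are clipped, and a wide moving average along each chromosome
#' converts gene-level noise into chromosome-scale signal. Concretely the
#' pipeline is
#'
#' 1. library-size normalise to counts-per-10k and take `log2(x + 1)`;
#' 2. subtract the per-gene mean over `reference_cell_ids`;
#' 3. clip residuals to `[-clip * sd_ref, +clip * sd_ref]`, where `sd_ref`
#'    is the pooled standard deviation of the reference residuals;
#' 4. within each chromosome, apply a centred moving average of
#'    `window_size` genes (windows truncate at chromosome ends);
#' 5. optionally subtract each cell's genome-wide median so a diploid
#'    baseline sits at 0.
#'
#' @param x An [expression_matrix()] or counts matrix (cells x genes).
#' @param annotation Tibble with `gene_id`, `chromosome`, `start` (and
#'   optionally `end`); genes absent from the annotation are dropped, and
#'   the output follows (chromosome, start) order with chromosomes in
#'   natural order (chr1..chr22, chrX, chrY, then others).
#' @param reference_cell_ids Character vector of normal-reference cells;
#'   must intersect the matrix rows.
#' @param window_size Odd moving-average width in genes (default 101).
#' @param clip Residual clip in pooled reference SDs (default 3); `Inf`
#'   disables clipping.
#' @param center_cells Subtract each cell's genome-wide median at the end
#'   (default `TRUE`).
#' @return An object of class `mplc_cnv`: list with `values` (cells x
#'   ordered-genes matrix of smoothed log2-scale relative estimates),
#'   `gene_order` (tibble: gene_id, chromosome, start) and
#'   `reference_cell_ids`.
#' @examples
#' cfg <- simulation_config(n_ref_cells = 40, n_tumor_cells = 40,
#'                          n_genes = 300, n_chromosomes = 3,
#'                          cnv_segments = list(list(chromosome = 1, start = 1,
#'                                                   end = 100, fold_change = 2)),
#'                          seed = 2)
#' sim <- simulate_counts(cfg)
#' refs <- sim$truth$cell_labels$cell_id[sim$truth$cell_labels$label == "reference"]
#' cnv <- compute_cnv_matrix(sim$matrix, sim$truth$annotation, refs,
#'                           window_size = 51)
#' @export
compute_cnv_matrix <- function(x, annotation, reference_cell_ids,
                               window_size = 101, clip = 3,
                               center_cells = TRUE) {
  counts <- if (inherits(x, "mplc_matrix")) x$counts else x
  window_size <- assert_count(window_size, "window_size")
  if (window_size %% 2 == 0) abort("`window_size` must be odd.")
  assert_scalar_number(clip, "clip", min = 0, max = Inf, allow_inf = TRUE)
  if (!length(reference_cell_ids)) abort("`reference_cell_ids` is empty.")
  ref_idx <- rownames(counts) %in% reference_cell_ids
  if (!any(ref_idx)) abort("No reference cell id matches the matrix rows.")

  ann <- as_tibble(annotation)
  ann <- ann[ann$gene_id %in% colnames(counts), ]
  if (!nrow(ann)) abort("No gene is shared between the matrix and the annotation.")
  ann <- ann[order(chromosome_rank(ann$chromosome), ann$start), ]

  expr <- lognormalize(counts[, ann$gene_id, drop = FALSE])

  ref_mean <- colMeans(expr[ref_idx, , drop = FALSE])
  resid <- sweep(expr, 2, ref_mean)

  if (is.finite(clip)) {
    sd_ref <- sd(as.numeric(resid[ref_idx, , drop = FALSE]))
    bound <- clip * sd_ref
    resid[resid > bound] <- bound
    resid[resid < -bound] <- -bound
  }

  smoothed <- resid
  for (chrom in unique(ann$chromosome)) {
    j <- which(ann$chromosome == chrom)
    smoothed[, j] <- row_moving_average(resid[, j, drop = FALSE], window_size)
  }
  if (center_cells) {
    smoothed <- sweep(smoothed, 1, apply(smoothed, 1, median))
  }
  structure(
    list(values = smoothed,
         gene_order = ann[, intersect(c("gene_id", "chromosome", "start"), names(ann))],
         reference_cell_ids = rownames(counts)[ref_idx]),
    class = "mplc_cnv")
}

#' @export
print.mplc_cnv <- function(x, ...) {
  cat(sprintf("<mplc_cnv> %d cells x %d ordered genes on %d chromosomes (%d reference cells)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$gene_order$chromosome)),
              length(x$reference_cell_ids)))
  invisible(x)
}

#' Per-cell CNV signal
#'
#' The mean of squared copy-number estimates across all genomic sites
#' (ordered genes) of one cell — a scalar burden measure that is 0 for a
#' flat profile and grows quadratically with deviation amplitude.
#'
#' @param cnv An `mplc_cnv` from [compute_cnv_matrix()], or a bare numeric
#'   matrix of CNV estimates (cells x genes).
#' @return Named numeric vector of non-negative per-cell signals.
#' @examples
#' compute_cnv_signal(rbind(c(0.1, -0.1, 0.2, 0)))  # 0.015
#' @export
compute_cnv_signal <- function(cnv) {
  v <- if (inherits(cnv, "mplc_cnv")) cnv$values else cnv
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) == 0) abort("CNV matrix has zero genes.")
  if (any(!is.finite(v))) abort("CNV matrix contains non-finite values.")
  rowMeans(v^2)
}

#' Per-cell CNV R-score
#'
#' Within each tumour group, the "typical" CNV pattern is the per-gene mean
#' profile of the `ceiling(top_fraction * n)` cells (at least 1) with the
#' highest CNV signal; each cell's R-score is the Pearson correlation of its
#' own profile with that consensus. Cells from the normal sample are scored
#' against their own group the same way. A degenerate correlation (constant
#' profile on either side) is defined as 0.
#'
#' @param cnv An `mplc_cnv` (or matrix with cell row names).
#' @param tumour_groups Named character vector, or tibble with `cell_id` and
#'   `group`, assigning every cell of the CNV matrix to exactly one group
#'   (typically the sample/lesion).
#' @param signals Optional precomputed [compute_cnv_signal()] values; must
#'   be named by cell.
#' @param top_fraction Fraction of highest-signal cells defining the
#'   consensus (default 0.05).
#' @return Tibble with `cell_id`, `group`, `cnv_signal`, `r_score`.
#' @export
compute_r_score <- function(cnv, tumour_groups, signals = NULL,
                            top_fraction = 0.05) {
  v <- if (inherits(cnv, "mplc_cnv")) cnv$values else cnv
  assert_scalar_number(top_fraction, "top_fraction", min = 1e-12, max = 1)
  if (is.data.frame(tumour_groups)) {
    tumour_groups <- setNames(tumour_groups$group, tumour_groups$cell_id)
  }
  cells <- rownames(v)
  if (is.null(cells)) abort("CNV matrix must have cell row names.")
  groups <- tumour_groups[cells]
  if (any(is.na(groups))) {
    abort(sprintf("%d cells have no tumour group assignment.", sum(is.na(groups))))
  }
  signals <- signals %||% compute_cnv_signal(v)
  signals <- signals[cells]

  r <- setNames(rep(NA_real_, length(cells)), cells)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) {
      warn(sprintf("Group '%s' has no cells; skipped.", g))
      next
    }
    k <- max(1L, ceiling(top_fraction * length(idx)))
    top <- idx[order(-signals[idx])][seq_len(k)]
    consensus <- colMeans(v[top, , drop = FALSE])
    sd_cons <- sd(consensus)
    for (i in idx) {
      prof <- v[i, ]
      r[i] <- if (sd_cons == 0 || sd(prof) == 0) 0 else cor(prof, consensus)
    }
  }
  tibble(cell_id = cells, group = unname(groups),
         cnv_signal = unname(signals), r_score = unname(r))
}

#' Classify cells as malignant, non-malignant or unresolved
#'
#' The two-threshold rule on (R-score, CNV signal): a cell is malignant when
#' `r_score >= r_threshold` and `cnv_signal >= s_threshold`; non-malignant
#' when `r_score <= r_threshold` and `cnv_signal <= s_threshold`; otherwise
#' unresolved. The malignant rule is evaluated first, so a cell sitting
#' exactly on both thresholds is called malignant.
#'
#' @param scores Tibble from [compute_r_score()] (columns `r_score`,
#'   `cnv_signal`), or a numeric vector of r-scores (then `cnv_signal` must
#'   be supplied).
#' @param cnv_signal Numeric vector of signals when `scores` is a vector.
#' @param r_threshold,s_threshold Classification thresholds, defaults
#'   `0.4` and `0.03`.
#' @return If `scores` is a tibble, the tibble with a `label` column added
#'   (class `mplc_malignancy`); otherwise a character vector of labels.
#' @examples
#' classify_malignancy(c(0.5, 0.1, 0.7, 0.4), c(0.05, 0.001, 0.01, 0.03))
#' @export
classify_malignancy <- function(scores, cnv_signal = NULL,
                                r_threshold = 0.4, s_threshold = 0.03) {
  if (is.data.frame(scores)) {
    r <- scores$r_score
    s <- scores$cnv_signal
  } else {
    r <- scores
    s <- cnv_signal
  }
  if (is.null(s) || length(r) != length(s)) {
    abort("r-scores and CNV signals must be paired vectors of equal length.")
  }
  if (any(!is.finite(r)) || any(!is.finite(s))) {
    abort("Non-finite r-score or CNV signal.")
  }
  label <- ifelse(r >= r_threshold & s >= s_threshold, "malignant",
           ifelse(r <= r_threshold & s <= s_threshold, "non_malignant",
                  "unresolved"))
  if (is.data.frame(scores)) {
    out <- mutate(scores, label = label)
    attr(out, "thresholds") <- c(r_threshold = r_threshold,
                                 s_threshold = s_threshold)
    class(out) <- c("mplc_malignancy", class(out))
    out
  } else {
    label
  }
}

#' @method tidy mplc_malignancy
#' @export
tidy.mplc_malignancy <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mplc_malignancy")
  attr(out, "thresholds") <- NULL
  out
}

#' @method glance mplc_malignancy
#' @export
glance.mplc_malignancy <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_malignant = sum(x$label == "malignant"),
    n_non_malignant = sum(x$label == "non_malignant"),
    n_unresolved = sum(x$label == "unresolved"),
    median_signal = median(x$cnv_signal),
    median_r_score = median(x$r_score)
  )
}
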