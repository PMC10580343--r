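#' @importFrom ggplot2 ggplot aes geom_tile geom_point geom_col geom_hline
#'   geom_vline scale_fill_gradient2 scale_fill_gradient labs theme_minimal
#'   facet_grid autoplot
NULL

#' Heat map of smoothed copy-number estimates
#'
#' Cells (rows, ordered by group then signal) against genome-ordered genes,
#' coloured by the smoothed log2-scale estimate; chromosome boundaries form
#' the facets. For large matrices a random subset of cells is drawn.
#'
#' @param cnv An `mplc_cnv` from [compute_cnv_matrix()].
#' @param max_cells Cell subsample cap (default 300, deterministic).
#' @return A ggplot object.
#' @export
plot_cnv_heatmap <- function(cnv, max_cells = 300) {
  stopifnot(inherits(cnv, "mplc_cnv"))
  v <- cnv$values
  cells <- rownames(v)
  if (length(cells) > max_cells) {
    keep <- cells[round(seq(1, length(cells), length.out = max_cells))]
    v <- v[keep, , drop = FALSE]
  }
  df <- tibble(
    cell = rep(rownames(v), times = ncol(v)),
    gene_index = rep(seq_len(ncol(v)), each = nrow(v)),
    chromosome = rep(cnv$gene_order$chromosome, each = nrow(v)),
    value = as.numeric(v)
  )
  df$chromosome <- factor(df$chromosome, levels = unique(cnv$gene_order$chromosome))
  ggplot(df, aes(x = .data$gene_index, y = .data$cell, fill = .data$value)) +
    geom_tile() +
    facet_grid(cols = ggplot2::vars(.data$chromosome),
               scales = "free_x", space = "free_x") +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = "genes in genomic order", y = NULL, fill = "log2 ratio") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_blank(),
                   panel.spacing = ggplot2::unit(0.1, "lines"))
}

#' Scatter of CNV signal vs R-score with classification thresholds
#'
#' @param object An `mplc_malignancy` tibble from [classify_malignancy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mplc_malignancy
#' @export
autoplot.mplc_malignancy <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% c(r_threshold = 0.4, s_threshold = 0.03)
  ggplot(object, aes(x = .data$r_score, y = .data$cnv_signal,
                     colour = .data$label)) +
    geom_point(alpha = 0.6, size = 0.8) +
    geom_vline(xintercept = thr[["r_threshold"]], linetype = "dashed") +
    geom_hline(yintercept = thr[["s_threshold"]], linetype = "dashed") +
    labs(x = "CNV R-score", y = "CNV signal", colour = NULL) +
    theme_minimal()
}

#' Stacked bars of per-sample cell-type proportions by pathology group
#'
#' @param object An `mplc_composition` from [composition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mplc_composition
#' @export
autoplot.mplc_composition <- function(object, ...) {
  ggplot(object$by_sample,
         aes(x = .data$sample, y = .data$proportion, fill = .data$cell_type)) +
    geom_col() +
    facet_grid(cols = ggplot2::vars(.data$group), scales = "free_x",
               space = "free_x") +
    labs(x = NULL, y = "proportion of cells", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tile heat map of pairwise repertoire overlap coefficients
#'
#' @param object An `mplc_overlap` matrix from [overlap_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mplc_overlap
#' @export
autoplot.mplc_overlap <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    a = rep(rownames(m), times = ncol(m)),
    b = rep(colnames(m), each = nrow(m)),
    overlap = as.numeric(m)
  )
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$overlap)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "overlap") +
    theme_minimal()
}

#' Tile map of significant-interaction counts per ordered cluster pair
#'
#' @param object An `mplc_network` from [interaction_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mplc_network
#' @export
autoplot.mplc_network <- function(object, ...) {
  ggplot(object$edges,
         aes(x = .data$cluster_a, y = .data$cluster_b,
             fill = .data$n_significant)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#2166ac") +
    labs(x = "sender (ligand)", y = "receiver (receptor)",
         fill = "significant\ninteractions") +
    theme_minimal()
}
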