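#' Cell-type composition per sample and pathology group
#'
#' Tallies cells per (sample, cell type), converts to within-sample
#' proportions, and averages those proportions within each pathology group.
#' The group average is the unweighted mean of the member samples'
#' proportion vectors (every sample counts equally, regardless of its cell
#' count); the pooled-cell proportion is also reported for comparison.
#'
#' @param meta Per-cell tibble with columns `sample`, `group` (e.g.
#'   `normal`, `AIS/MIA`, `IAC`) and `cell_type`. Column names can be
#'   remapped via the arguments.
#' @param sample_col,group_col,cell_type_col Column names in `meta`.
#' @return Object of class `mplc_composition`: list with `by_sample`
#'   (sample, group, cell_type, n, proportion — proportions sum to 1 per
#'   sample), `group_mean` (group, cell_type, mean_proportion — unweighted
#'   across samples) and `group_pooled` (group, cell_type,
#'   pooled_proportion).
#' @examples
#' meta <- tibble::tibble(sample = rep(c("s1", "s2"), each = 10),
#'                        group = rep(c("normal", "IAC"), each = 10),
#'                        cell_type = rep(c("T", "B"), 10))
#' composition(meta)$group_mean
#' @export
composition <- function(meta, sample_col = "sample", group_col = "group",
                        cell_type_col = "cell_type") {
  meta <- as_tibble(meta)
  cols <- c(sample_col, group_col, cell_type_col)
  missing_cols <- setdiff(cols, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  meta <- meta %>%
    select(sample = all_of(sample_col), group = all_of(group_col),
           cell_type = all_of(cell_type_col))
  bad <- which(is.na(meta$sample) | is.na(meta$group) | is.na(meta$cell_type))
  if (length(bad)) {
    abort(sprintf("Unlabeled cells at rows: %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  all_types <- sort(unique(meta$cell_type))
  by_sample <- meta %>%
    count(.data$sample, .data$group, .data$cell_type, name = "n") %>%
    group_by(.data$sample) %>%
    tidyr::complete(cell_type = all_types, fill = list(n = 0L)) %>%
    tidyr::fill("group", .direction = "downup") %>%
    mutate(proportion = .data$n / sum(.data$n)) %>%
    ungroup()
  group_mean <- by_sample %>%
    group_by(.data$group, .data$cell_type) %>%
    summarise(mean_proportion = mean(.data$proportion), .groups = "drop")
  group_pooled <- by_sample %>%
    group_by(.data$group, .data$cell_type) %>%
    summarise(n = sum(.data$n), .groups = "drop_last") %>%
    mutate(pooled_proportion = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select("group", "cell_type", "pooled_proportion")
  structure(list(by_sample = by_sample, group_mean = group_mean,
                 group_pooled = group_pooled),
            class = "mplc_composition")
}

#' @export
print.mplc_composition <- function(x, ...) {
  cat(sprintf("<mplc_composition> %d samples, %d groups, %d cell types\n",
              length(unique(x$by_sample$sample)),
              length(unique(x$by_sample$group)),
              length(unique(x$by_sample$cell_type))))
  print(x$group_mean, n = 12)
  invisible(x)
}

#' Monotone trend of a cell type across ordered groups
#'
#' Reports whether the group-mean proportion of one cell type is strictly
#' increasing, strictly decreasing, or neither along an ordered group axis
#' (by default normal -> AIS/MIA -> IAC).
#'
#' @param comp An [composition()] result (or its `group_mean` tibble).
#' @param cell_type Cell type to inspect.
#' @param group_order Ordered character vector of groups; all must be
#'   present.
#' @return One-row tibble: `cell_type`, `trend` (increasing / decreasing /
#'   neither) and one `mean_<group>` column per group.
#' @export
trend_flags <- function(comp, cell_type,
                        group_order = c("normal", "AIS/MIA", "IAC")) {
  gm <- if (inherits(comp, "mplc_composition")) comp$group_mean else as_tibble(comp)
  missing_groups <- setdiff(group_order, gm$group)
  if (length(missing_groups)) {
    abort(paste0("Groups absent from the table: ",
                 paste(missing_groups, collapse = ", ")))
  }
  rows <- gm[gm$cell_type == cell_type, ]
  if (!nrow(rows)) abort(sprintf("Cell type '%s' not found.", cell_type))
  means <- vapply(group_order, function(g) {
    v <- rows$mean_proportion[rows$group == g]
    if (length(v)) v else 0
  }, numeric(1))
  d <- diff(means)
  trend <- if (all(d > 0)) "increasing" else if (all(d < 0)) "decreasing" else "neither"
  out <- tibble(cell_type = cell_type, trend = trend)
  for (g in group_order) out[[paste0("mean_", g)]] <- means[[g]]
  out
}
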