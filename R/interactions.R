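#' Fraction of cells expressing a gene, per cluster
#'
#' A cell "expresses" a gene when its count is >= 1. A ligand-receptor pair
#' is only eligible for testing from cluster A to cluster B when the ligand
#' is expressed by strictly more than `min_fraction` of A's cells and the
#' receptor by strictly more than `min_fraction` of B's cells (default 30%,
#' so exactly 30% fails).
#'
#' @param x An [expression_matrix()] or counts matrix (cells x genes).
#' @param cluster_labels Character vector of cluster labels, one per cell
#'   (or named by cell id).
#' @param genes Genes to evaluate; default all.
#' @return Tibble `cluster`, `gene`, `expressing_fraction`.
#' @export
expressing_fraction <- function(x, cluster_labels, genes = NULL) {
  counts <- if (inherits(x, "mplc_matrix")) x$counts else x
  labels <- align_labels(cluster_labels, counts)
  genes <- genes %||% colnames(counts)
  missing_genes <- setdiff(genes, colnames(counts))
  if (length(missing_genes)) {
    abort(paste0("Genes absent from the matrix: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  detected <- counts[, genes, drop = FALSE] >= 1
  out <- lapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    if (!length(idx)) abort(sprintf("Cluster '%s' is empty.", cl))
    tibble(cluster = cl, gene = genes,
           expressing_fraction = unname(Matrix::colMeans(detected[idx, , drop = FALSE])))
  })
  bind_rows(out)
}

align_labels <- function(cluster_labels, counts) {
  if (!is.null(names(cluster_labels))) {
    labels <- cluster_labels[rownames(counts)]
    if (any(is.na(labels))) abort("Some cells have no cluster label.")
    return(unname(labels))
  }
  if (length(cluster_labels) != nrow(counts)) {
    abort("`cluster_labels` must have one label per cell.")
  }
  as.character(cluster_labels)
}

# z-scale each gene across all cells on the log-normalised scale
scaled_expression <- function(x, genes) {
  m <- lognormalize(x)[, genes, drop = FALSE]
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s == 0] <- 1   # constant gene -> all-zero z-scores
  sweep(sweep(m, 2, mu), 2, s, `/`)
}

#' Ligand-receptor interaction score between two clusters
#'
#' On library-size log-normalised, gene-wise z-scaled expression, the score
#' of pair (ligand, receptor) from cluster A to cluster B is the mean of the
#' ligand's average scaled expression in A and the receptor's average scaled
#' expression in B.
#'
#' @param x An [expression_matrix()].
#' @param cluster_labels Per-cell cluster labels.
#' @param ligand,receptor Gene ids.
#' @param cluster_a,cluster_b Sender (ligand) and receiver (receptor)
#'   clusters.
#' @return A single numeric score.
#' @export
interaction_score <- function(x, cluster_labels, ligand, receptor,
                              cluster_a, cluster_b) {
  counts <- if (inherits(x, "mplc_matrix")) x$counts else x
  labels <- align_labels(cluster_labels, counts)
  z <- scaled_expression(counts, unique(c(ligand, receptor)))
  idx_a <- which(labels == cluster_a)
  idx_b <- which(labels == cluster_b)
  if (!length(idx_a) || !length(idx_b)) abort("Empty sender or receiver cluster.")
  (mean(z[idx_a, ligand]) + mean(z[idx_b, receptor])) / 2
}

#' Permutation test and interaction table for a ligand-receptor pair list
#'
#' For every pair and every ordered cluster pair (A, B), applies the
#' expressing-fraction eligibility filter, computes the interaction score,
#' and tests it against a null built by jointly shuffling the cluster
#' labels of all cells `n_perm` times. The p-value uses a pseudocount,
#' `p = (1 + #\{permuted >= observed\}) / (1 + n_perm)`, so it is never 0.
#' Ineligible combinations are reported with `tested = FALSE` and `NA`
#' score/p-value.
#'
#' @param x An [expression_matrix()].
#' @param cluster_labels Per-cell cluster labels.
#' @param pairs Tibble with columns `ligand`, `receptor` and optionally
#'   `pair_id`; see [demo_lr_pairs()] for a small built-in list.
#' @param n_perm Number of label permutations (default 1000).
#' @param min_fraction Expressing-fraction eligibility threshold
#'   (default 0.30, strict).
#' @param seed Integer seed for the permutations.
#' @param same_cluster Also test A == B pairs (default `FALSE`).
#' @return Tibble of class `mplc_interactions`: `pair_id`, `ligand`,
#'   `receptor`, `cluster_a`, `cluster_b`, `tested`, `score`, `p_value`.
#' @export
test_interactions <- function(x, cluster_labels, pairs, n_perm = 1000,
                              min_fraction = 0.30, seed = 1L,
                              same_cluster = FALSE) {
  counts <- if (inherits(x, "mplc_matrix")) x$counts else x
  n_perm <- assert_count(n_perm, "n_perm")
  assert_scalar_number(min_fraction, "min_fraction", 0, 1)
  labels <- align_labels(cluster_labels, counts)
  pairs <- as_tibble(pairs)
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    abort("`pairs` needs `ligand` and `receptor` columns.")
  }
  if (!"pair_id" %in% names(pairs)) {
    pairs$pair_id <- paste(pairs$ligand, pairs$receptor, sep = "_")
  }
  genes <- unique(c(pairs$ligand, pairs$receptor))
  missing_genes <- setdiff(genes, colnames(counts))
  if (length(missing_genes)) {
    abort(paste0("Pair genes absent from the matrix: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  clusters <- sort(unique(labels))
  frac <- expressing_fraction(counts, labels, genes)
  # one row per cluster, one column per gene
  frac_m <- t(matrix(frac$expressing_fraction, nrow = length(genes),
                     dimnames = list(genes, clusters)))
  z <- scaled_expression(counts, genes)
  idx_by_cluster <- lapply(setNames(clusters, clusters),
                           function(cl) which(labels == cl))

  grid <- expand.grid(cluster_a = clusters, cluster_b = clusters,
                      stringsAsFactors = FALSE)
  if (!same_cluster) grid <- grid[grid$cluster_a != grid$cluster_b, ]

  n_cells <- nrow(z)
  withr::with_seed(seed, {
    rows <- vector("list", nrow(pairs) * nrow(grid))
    k <- 0L
    for (p in seq_len(nrow(pairs))) {
      lig <- pairs$ligand[p]
      rec <- pairs$receptor[p]
      zl <- z[, lig]
      zr <- z[, rec]
      for (gidx in seq_len(nrow(grid))) {
        a <- grid$cluster_a[gidx]
        b <- grid$cluster_b[gidx]
        k <- k + 1L
        eligible <- frac_m[a, lig] > min_fraction && frac_m[b, rec] > min_fraction
        if (!eligible) {
          rows[[k]] <- tibble(pair_id = pairs$pair_id[p], ligand = lig,
                              receptor = rec, cluster_a = a, cluster_b = b,
                              tested = FALSE, score = NA_real_,
                              p_value = NA_real_)
          next
        }
        ia <- idx_by_cluster[[a]]
        ib <- idx_by_cluster[[b]]
        obs <- (mean(zl[ia]) + mean(zr[ib])) / 2
        # joint label shuffle: one permutation of all cells per iteration
        perm <- matrix(0, nrow = n_cells, ncol = n_perm)
        for (q in seq_len(n_perm)) perm[, q] <- sample.int(n_cells)
        mean_a <- colMeans(matrix(zl[perm[ia, , drop = FALSE]], nrow = length(ia)))
        mean_b <- colMeans(matrix(zr[perm[ib, , drop = FALSE]], nrow = length(ib)))
        null_scores <- (mean_a + mean_b) / 2
        pval <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
        rows[[k]] <- tibble(pair_id = pairs$pair_id[p], ligand = lig,
                            receptor = rec, cluster_a = a, cluster_b = b,
                            tested = TRUE, score = obs, p_value = pval)
      }
    }
    out <- bind_rows(rows)
  })
  class(out) <- c("mplc_interactions", class(out))
  out
}

#' Significant-interaction network between clusters
#'
#' Tallies the tested pairs with `p_value < alpha` per ordered (A, B)
#' cluster pair, the undirected tally per unordered pair, and a per-cluster
#' node weight (total significant interactions touching the cluster).
#'
#' @param results An `mplc_interactions` tibble from [test_interactions()].
#' @param alpha Significance level (default 0.05).
#' @return List of class `mplc_network` with `edges` (cluster_a, cluster_b,
#'   n_significant), `edges_undirected` and `nodes` (cluster, weight).
#' @export
interaction_network <- function(results, alpha = 0.05) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  results <- as_tibble(results)
  sig <- results %>%
    filter(.data$tested) %>%
    mutate(significant = .data$p_value < alpha)
  edges <- sig %>%
    group_by(.data$cluster_a, .data$cluster_b) %>%
    summarise(n_significant = sum(.data$significant), .groups = "drop")
  undirected <- sig %>%
    mutate(u = pmin(.data$cluster_a, .data$cluster_b),
           v = pmax(.data$cluster_a, .data$cluster_b)) %>%
    group_by(.data$u, .data$v) %>%
    summarise(n_significant = sum(.data$significant), .groups = "drop") %>%
    rename(cluster_a = "u", cluster_b = "v")
  clusters <- sort(unique(c(edges$cluster_a, edges$cluster_b)))
  nodes <- tibble(
    cluster = clusters,
    weight = vapply(unname(clusters), function(cl) {
      sum(edges$n_significant[edges$cluster_a == cl | edges$cluster_b == cl])
    }, numeric(1), USE.NAMES = FALSE)
  )
  structure(list(edges = edges, edges_undirected = undirected, nodes = nodes,
                 alpha = alpha),
            class = "mplc_network")
}

#' @export
print.mplc_network <- function(x, ...) {
  cat(sprintf("<mplc_network> %d clusters, %d directed edges, alpha = %g\n",
              nrow(x$nodes), nrow(x$edges), x$alpha))
  print(x$edges, n = 10)
  invisible(x)
}

#' A small built-in ligand-receptor pair list for demonstrations
#'
#' Synthetic pair ids over generic gene names; real analyses should supply
#' a curated database as a two-column table.
#'
#' @param genes Optional gene pool to draw pair members from.
#' @param n_pairs Number of pairs (default 20).
#' @param seed Seed for the draw.
#' @return Tibble `ligand`, `receptor`, `pair_id`.
#' @export
demo_lr_pairs <- function(genes = NULL, n_pairs = 20, seed = 1L) {
  n_pairs <- assert_count(n_pairs, "n_pairs")
  withr::with_seed(seed, {
    if (is.null(genes)) genes <- sprintf("gene%04d", 1:200)
    if (length(genes) < 2 * n_pairs) {
      abort("Not enough genes to build that many disjoint pairs.")
    }
    picked <- sample(genes, 2 * n_pairs)
    tibble(ligand = picked[seq_len(n_pairs)],
           receptor = picked[n_pairs + seq_len(n_pairs)],
           pair_id = paste(picked[seq_len(n_pairs)],
                           picked[n_pairs + seq_len(n_pairs)], sep = "_"))
  })
}

#' @method tidy mplc_interactions
#' @export
tidy.mplc_interactions <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mplc_interactions")
  out
}

#' @method glance mplc_interactions
#' @export
glance.mplc_interactions <- function(x, ...) {
  tested <- x[x$tested, ]
  tibble(
    n_combinations = nrow(x),
    n_tested = nrow(tested),
    n_significant_05 = sum(tested$p_value < 0.05),
    min_p = if (nrow(tested)) min(tested$p_value) else NA_real_
  )
}
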