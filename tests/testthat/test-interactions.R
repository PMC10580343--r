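two_cluster_matrix <- function(n_per = 50, n_genes = 30, seed = 61, lambda = 3) {
  counts <- toy_counts(2 * n_per, n_genes, seed = seed, lambda = lambda)
  labels <- setNames(rep(c("A", "B"), each = n_per), rownames(counts))
  list(counts = counts, labels = labels)
}

test_that("expressing fraction counts cells with at least one count, per cluster", {
  m <- matrix(0L, 200, 3, dimnames = list(sprintf("c%03d", 1:200),
                                          c("silent", "edge31", "edge30")))
  m[1:31, "edge31"] <- 1L      # 31% of cluster A
  m[1:30, "edge30"] <- 1L      # 30% of cluster A
  labels <- setNames(rep(c("A", "B"), each = 100), rownames(m))
  out <- expressing_fraction(m, labels)
  fr <- function(cl, g) out$expressing_fraction[out$cluster == cl & out$gene == g]
  expect_equal(fr("A", "silent"), 0)
  expect_equal(fr("A", "edge31"), 0.31)
  expect_equal(fr("A", "edge30"), 0.30)
  # strict > 0.30: 31% is eligible, exactly 30% is not
  expect_true(fr("A", "edge31") > 0.30)
  expect_false(fr("A", "edge30") > 0.30)
})

test_that("interaction score equals the hand-computed mean of scaled means", {
  tc <- two_cluster_matrix(n_per = 10, n_genes = 6, seed = 3)
  got <- interaction_score(tc$counts, tc$labels, "g001", "g002", "A", "B")
  # oracle: log-normalise, z-scale, average the two cluster means
  ln <- log2(tc$counts / rowSums(tc$counts) * 1e4 + 1)
  z <- scale(ln)
  want <- (mean(z[1:10, "g001"]) + mean(z[11:20, "g002"])) / 2
  expect_equal(got, want, tolerance = 1e-9)
  # mirrored pair with swapped clusters scores identically
  mirrored <- interaction_score(tc$counts, tc$labels, "g002", "g001", "B", "A")
  expect_equal(mirrored, got, tolerance = 1e-12)
})

test_that("permutation p-values are deterministic under a seed and bounded below", {
  tc <- two_cluster_matrix(n_per = 20, n_genes = 10, seed = 5)
  # plant a strong ligand signal in cluster A
  tc$counts[1:20, "g001"] <- tc$counts[1:20, "g001"] + 50L
  pairs <- tibble::tibble(ligand = "g001", receptor = "g002", pair_id = "p1")
  r1 <- test_interactions(tc$counts, tc$labels, pairs, n_perm = 200, seed = 9)
  r2 <- test_interactions(tc$counts, tc$labels, pairs, n_perm = 200, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  ab <- r1[r1$cluster_a == "A" & r1$cluster_b == "B", ]
  # observed far above every permuted score -> the pseudocount floor
  expect_equal(ab$p_value, 1 / 201)
})

test_that("p-values are invariant to permuting the cell order of the input", {
  tc <- two_cluster_matrix(n_per = 15, n_genes = 8, seed = 21)
  pairs <- tibble::tibble(ligand = c("g001", "g003"),
                          receptor = c("g002", "g004"))
  r1 <- test_interactions(tc$counts, tc$labels, pairs, n_perm = 500, seed = 4)
  withr::with_seed(8, ord <- sample.int(nrow(tc$counts)))
  r2 <- test_interactions(tc$counts[ord, ], tc$labels[rownames(tc$counts)[ord]],
                          pairs, n_perm = 500, seed = 4)
  merged <- dplyr::inner_join(r1, r2, by = c("pair_id", "cluster_a", "cluster_b"))
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-12)
  # same null law either way; identical seeds give identical p-values because
  # the permutation distribution depends only on (values, cluster sizes)
  expect_equal(merged$p_value.x, merged$p_value.y, tolerance = 0.1)
})

test_that("ineligible pairs are reported but not tested", {
  tc <- two_cluster_matrix(n_per = 10, n_genes = 5, seed = 33)
  tc$counts[, "g005"] <- 0L
  pairs <- tibble::tibble(ligand = "g005", receptor = "g001")
  out <- test_interactions(tc$counts, tc$labels, pairs, n_perm = 50, seed = 1)
  expect_true(all(!out$tested))
  expect_true(all(is.na(out$p_value)))
})

test_that("raising the eligibility threshold never adds eligible pairs", {
  tc <- two_cluster_matrix(n_per = 30, n_genes = 20, seed = 41, lambda = 0.7)
  pairs <- demo_lr_pairs(genes = colnames(tc$counts), n_pairs = 10, seed = 2)
  eligible_at <- function(thr) {
    out <- test_interactions(tc$counts, tc$labels, pairs, n_perm = 10,
                             min_fraction = thr, seed = 1)
    sum(out$tested)
  }
  counts <- vapply(c(0.1, 0.3, 0.5, 0.9), eligible_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("Monte-Carlo p matches exhaustive enumeration on a six-cell toy", {
  counts <- matrix(c(5, 9, 2, 0, 3, 7,
                     1, 4, 6, 8, 2, 5), ncol = 2,
                   dimnames = list(paste0("c", 1:6), c("lig", "rec")))
  labels <- setNames(rep(c("A", "B"), each = 3), rownames(counts))
  out <- test_interactions(counts, labels,
                           tibble::tibble(ligand = "lig", receptor = "rec"),
                           n_perm = 4000, seed = 30)
  ab <- out[out$cluster_a == "A" & out$cluster_b == "B", ]
  # oracle: enumerate all 20 assignments of cells to the A positions
  ln <- log2(counts / rowSums(counts) * 1e4 + 1)
  z <- scale(ln)
  obs <- (mean(z[1:3, "lig"]) + mean(z[4:6, "rec"])) / 2
  combos <- utils::combn(6, 3)
  null_scores <- apply(combos, 2, function(ia) {
    (mean(z[ia, "lig"]) + mean(z[setdiff(1:6, ia), "rec"])) / 2
  })
  exact_frac <- mean(null_scores >= obs)
  # Monte-Carlo estimate of P(null >= obs) with pseudocount; compare within
  # a generous binomial CI around the exhaustive value
  expect_lt(abs(ab$p_value - exact_frac), 0.05)
  expect_equal(ab$score, obs, tolerance = 1e-9)
})

test_that("network tallies equal a brute-force filter-and-count", {
  res <- tibble::tibble(
    pair_id = sprintf("p%d", 1:8),
    ligand = "l", receptor = "r",
    cluster_a = c("A", "A", "B", "B", "A", "C", "C", "B"),
    cluster_b = c("B", "B", "A", "C", "C", "A", "B", "A"),
    tested = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    score = 1,
    p_value = c(0.01, 0.2, 0.03, 0.04, 0.5, 0.001, NA, 0.02))
  class(res) <- c("mplc_interactions", class(res))
  net <- interaction_network(res, alpha = 0.05)
  # oracle tally over tested rows with p < alpha
  want <- table(paste(res$cluster_a, res$cluster_b)[res$tested & res$p_value < 0.05])
  for (nm in names(want)) {
    parts <- strsplit(nm, " ")[[1]]
    expect_equal(net$edges$n_significant[net$edges$cluster_a == parts[1] &
                                         net$edges$cluster_b == parts[2]],
                 as.numeric(want[[nm]]))
  }
  # node weight = sum of incident directed edge counts
  for (cl in net$nodes$cluster) {
    expect_equal(net$nodes$weight[net$nodes$cluster == cl],
                 sum(net$edges$n_significant[net$edges$cluster_a == cl |
                                             net$edges$cluster_b == cl]))
  }
  # with alpha = 0 nothing is significant
  net0 <- interaction_network(res, alpha = 1e-12)
  expect_true(all(net0$edges$n_significant == 0))
})

test_that("undirected tally merges mirrored cluster pairs", {
  res <- tibble::tibble(
    pair_id = c("p1", "p2"), ligand = "l", receptor = "r",
    cluster_a = c("A", "B"), cluster_b = c("B", "A"),
    tested = TRUE, score = 1, p_value = c(0.01, 0.02))
  net <- interaction_network(res)
  expect_equal(nrow(net$edges_undirected), 1)
  expect_equal(net$edges_undirected$n_significant, 2)
})
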