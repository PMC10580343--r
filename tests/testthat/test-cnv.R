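test_that("moving average matches a brute-force window oracle", {
  withr::with_seed(31, {
    m <- matrix(rnorm(7 * 20), 7, 20)
  })
  for (w in c(1, 3, 5, 11)) {
    got <- mplckit:::row_moving_average(m, w)
    want <- t(apply(m, 1, oracle_moving_average, w = w))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("smoothed values on a tiny single-chromosome case equal hand computation", {
  # 2 cells x 5 genes, one chromosome, window 3, no clip, no median centering
  counts <- rbind(c(4, 0, 2, 6, 8),
                  c(2, 2, 2, 2, 2))
  dimnames(counts) <- list(c("ref1", "tum1"), paste0("g", 1:5))
  ann <- tibble::tibble(gene_id = paste0("g", 1:5), chromosome = "chr1",
                        start = 1:5, end = 1:5)
  cnv <- compute_cnv_matrix(counts, ann, "ref1", window_size = 3,
                            clip = Inf, center_cells = FALSE)
  # oracle: recompute every stage directly
  ln <- log2(counts / rowSums(counts) * 1e4 + 1)
  resid <- sweep(ln, 2, ln["ref1", ])
  want <- t(apply(resid, 1, oracle_moving_average, w = 3))
  dimnames(want) <- dimnames(resid)
  expect_equal(cnv$values, want, tolerance = 1e-9)
})

test_that("reference cells centre to zero per gene before median centering", {
  sim <- small_cnv_sim()
  refs <- sim$truth$cell_labels$cell_id[sim$truth$cell_labels$label == "reference"]
  cnv <- compute_cnv_matrix(sim$matrix, sim$truth$annotation, refs,
                            window_size = 1, clip = Inf, center_cells = FALSE)
  ref_means <- colMeans(cnv$values[refs, ])
  expect_lt(max(abs(ref_means)), 1e-9)
})

test_that("gene order follows natural chromosome order and position", {
  counts <- toy_counts(4, 6, seed = 1)
  ann <- tibble::tibble(
    gene_id = colnames(counts),
    chromosome = c("chr10", "chr2", "chr2", "chrX", "chr1", "chr1"),
    start = c(5L, 100L, 50L, 1L, 7L, 3L), end = c(6L, 101L, 51L, 2L, 8L, 4L))
  cnv <- compute_cnv_matrix(counts, ann, rownames(counts)[1:2], window_size = 1)
  expect_identical(cnv$gene_order$chromosome,
                   c("chr1", "chr1", "chr2", "chr2", "chr10", "chrX"))
  expect_identical(cnv$gene_order$start, c(3L, 7L, 50L, 100L, 5L, 1L))
})

test_that("planted gain lifts segment CNV values above off-segment values", {
  sim <- small_cnv_sim()
  labels <- sim$truth$cell_labels
  refs <- labels$cell_id[labels$label == "reference"]
  cnv <- compute_cnv_matrix(sim$matrix, sim$truth$annotation, refs,
                            window_size = 51)
  tum <- rownames(cnv$values) %in% labels$cell_id[labels$label == "tumor"]
  gain <- cnv$gene_order$chromosome == "chr1"
  loss <- cnv$gene_order$chromosome == "chr2"
  off <- !(gain | loss)
  expect_gt(mean(cnv$values[tum, gain]), mean(cnv$values[tum, off]))
  expect_lt(mean(cnv$values[tum, loss]), mean(cnv$values[tum, off]))
})

test_that("null simulation leaves tumor and reference CNV magnitudes indistinguishable", {
  cfg <- simulation_config(n_ref_cells = 80, n_tumor_cells = 80, n_genes = 600,
                           n_chromosomes = 6, cnv_segments = list(), seed = 12)
  sim <- simulate_counts(cfg)
  labels <- sim$truth$cell_labels
  refs <- labels$cell_id[labels$label == "reference"]
  cnv <- compute_cnv_matrix(sim$matrix, sim$truth$annotation, refs)
  tum <- rownames(cnv$values) %in% labels$cell_id[labels$label == "tumor"]
  p <- stats::t.test(rowMeans(abs(cnv$values[tum, ])),
                     rowMeans(abs(cnv$values[!tum, ])))$p.value
  expect_gt(p, 0.01)
})

test_that("CNV signal is the mean square of the profile", {
  expect_equal(unname(compute_cnv_signal(rbind(c(0.1, -0.1, 0.2, 0)))), 0.015)
  expect_equal(unname(compute_cnv_signal(rbind(rep(0, 10)))), 0)
  # homogeneity: scaling a profile by c scales the signal by c^2
  withr::with_seed(3, v <- rnorm(20))
  expect_equal(unname(compute_cnv_signal(rbind(3 * v))),
               9 * unname(compute_cnv_signal(rbind(v))))
  expect_error(compute_cnv_signal(matrix(numeric(0), 1, 0)), "zero genes")
  expect_error(compute_cnv_signal(rbind(c(1, NA))), "non-finite")
})

test_that("R-scores equal a direct Pearson computation against the group consensus", {
  withr::with_seed(7, {
    v <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(sprintf("c%02d", 1:10), sprintf("g%02d", 1:30)))
  })
  groups <- setNames(rep("tumor_1", 10), rownames(v))
  sc <- compute_r_score(v, groups, top_fraction = 0.05)
  # ceil(0.05 * 10) = 1: consensus is the single highest-signal cell
  sig <- rowMeans(v^2)
  consensus <- v[which.max(sig), ]
  for (i in 1:10) {
    expect_equal(sc$r_score[sc$cell_id == rownames(v)[i]],
                 oracle_pearson(v[i, ], consensus), tolerance = 1e-9)
  }
  # a cell identical to the consensus scores exactly 1
  expect_equal(sc$r_score[which.max(sig)], 1)
})

test_that("consensus size is ceil(top_fraction * n) with a floor of one cell", {
  withr::with_seed(8, {
    v <- matrix(rnorm(20 * 15), 20, 15,
                dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:15)))
  })
  groups <- setNames(rep("g1", 20), rownames(v))
  # 20 cells at 5% -> exactly 1 consensus cell
  sig <- rowMeans(v^2)
  sc <- compute_r_score(v, groups, top_fraction = 0.05)
  top_cell <- rownames(v)[which.max(sig)]
  expect_equal(sc$r_score[sc$cell_id == top_cell], 1)
  # 21st cell would flip to ceil(1.05) = 2; emulate by top_fraction just above
  sc2 <- compute_r_score(v, groups, top_fraction = 0.051)
  top2 <- rownames(v)[order(-sig)][1:2]
  consensus2 <- colMeans(v[top2, ])
  expect_equal(sc2$r_score[sc2$cell_id == top2[1]],
               oracle_pearson(v[top2[1], ], consensus2), tolerance = 1e-9)
})

test_that("degenerate flat profiles get r-score zero and classify non-malignant", {
  v <- rbind(flat = rep(0, 10), vary = c(rep(1, 5), rep(-1, 5)))
  colnames(v) <- paste0("g", 1:10)
  sc <- compute_r_score(v, setNames(rep("s", 2), rownames(v)))
  expect_equal(sc$r_score[sc$cell_id == "flat"], 0)
  calls <- classify_malignancy(sc)
  expect_equal(calls$label[calls$cell_id == "flat"], "non_malignant")
})

test_that("malignancy rule reproduces the threshold semantics exactly", {
  expect_equal(classify_malignancy(0.5, 0.05), "malignant")
  expect_equal(classify_malignancy(0.1, 0.001), "non_malignant")
  expect_equal(classify_malignancy(0.7, 0.01), "unresolved")
  expect_equal(classify_malignancy(0.1, 0.05), "unresolved")
  # exact boundary satisfies both rules; malignant is evaluated first
  expect_equal(classify_malignancy(0.4, 0.03), "malignant")
  expect_error(classify_malignancy(NA_real_, 0.1), "finite")
})

test_that("every finite score pair receives exactly one label", {
  withr::with_seed(44, {
    r <- runif(200, -1, 1)
    s <- runif(200, 0, 0.1)
  })
  labels <- classify_malignancy(r, s)
  expect_true(all(labels %in% c("malignant", "non_malignant", "unresolved")))
  expect_length(labels, 200)
})

test_that("classifier recovers planted malignancy at a detectable operating point", {
  sim <- small_cnv_sim()
  labels <- sim$truth$cell_labels
  refs <- labels$cell_id[labels$label == "reference"]
  cnv <- compute_cnv_matrix(sim$matrix, sim$truth$annotation, refs)
  groups <- setNames(sim$matrix$cell_meta$sample, sim$matrix$cell_meta$cell_id)
  calls <- classify_malignancy(compute_r_score(cnv, groups))
  truth <- labels$label[match(calls$cell_id, labels$cell_id)]
  expect_gte(mean(calls$label[truth == "tumor"] == "malignant"), 0.9)
  expect_lte(mean(calls$label[truth == "reference"] == "malignant"), 0.05)
})

test_that("null simulation stays under the malignant false-positive budget", {
  # null control at the genome scale the classifier is calibrated for
  cfg <- simulation_config(n_ref_cells = 200, n_tumor_cells = 200, n_genes = 5000,
                           n_chromosomes = 22, cnv_segments = list(), seed = 42)
  sim <- simulate_counts(cfg)
  labels <- sim$truth$cell_labels
  refs <- labels$cell_id[labels$label == "reference"]
  cnv <- compute_cnv_matrix(sim$matrix, sim$truth$annotation, refs)
  groups <- setNames(sim$matrix$cell_meta$sample, sim$matrix$cell_meta$cell_id)
  calls <- classify_malignancy(compute_r_score(cnv, groups))
  truth <- labels$label[match(calls$cell_id, labels$cell_id)]
  expect_lte(mean(calls$label[truth == "tumor"] == "malignant"), 0.05)
})

test_that("input validation rejects bad windows and missing references", {
  counts <- toy_counts(6, 10, seed = 5)
  ann <- tibble::tibble(gene_id = colnames(counts), chromosome = "chr1",
                        start = 1:10, end = 1:10)
  expect_error(compute_cnv_matrix(counts, ann, rownames(counts)[1],
                                  window_size = 4), "odd")
  expect_error(compute_cnv_matrix(counts, ann, "nope"), "reference")
  bad_ann <- tibble::tibble(gene_id = "zzz", chromosome = "chr1", start = 1, end = 1)
  expect_error(compute_cnv_matrix(counts, bad_ann, rownames(counts)[1]), "shared")
})
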