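test_that("gene annotation spreads genes evenly with remainder to earliest chromosomes", {
  ann <- generate_gene_annotation(10, 2)
  expect_equal(as.integer(table(ann$chromosome)[c("chr1", "chr2")]), c(5L, 5L))
  expect_true(all(diff(ann$start[ann$chromosome == "chr1"]) > 0))

  ann2 <- generate_gene_annotation(7, 3)
  expect_equal(as.integer(table(ann2$chromosome)[c("chr1", "chr2", "chr3")]),
               c(3L, 2L, 2L))

  ann3 <- generate_gene_annotation(1000, 22)
  expect_equal(sum(table(ann3$chromosome)), 1000L)
  expect_equal(length(unique(ann3$gene_id)), 1000L)

  expect_error(generate_gene_annotation(0, 1), "integer")
  expect_error(generate_gene_annotation(3, 5), ">=")
})

test_that("annotation generation is deterministic", {
  expect_identical(generate_gene_annotation(50, 7), generate_gene_annotation(50, 7))
})

test_that("simulated counts have configured dimensions and aligned truth", {
  cfg <- simulation_config(n_ref_cells = 30, n_tumor_cells = 20, n_genes = 120,
                           n_chromosomes = 4, n_mito_genes = 5, seed = 3)
  sim <- simulate_counts(cfg)
  expect_equal(dim(sim$matrix), c(50, 125))
  expect_equal(sum(startsWith(colnames(sim$matrix$counts), "MT-")), 5)
  # truth labels partition the cells
  expect_setequal(sim$truth$cell_labels$cell_id, rownames(sim$matrix$counts))
  expect_equal(sum(sim$truth$cell_labels$label == "reference"), 30)
  expect_equal(sum(sim$truth$cell_labels$label == "tumor"), 20)
  # truth fold vector aligns with annotation gene order
  expect_identical(names(sim$truth$gene_fold), sim$truth$annotation$gene_id)
})

test_that("same seed reproduces identical outputs, different seed does not", {
  cfg <- simulation_config(n_ref_cells = 20, n_tumor_cells = 20, n_genes = 80,
                           n_chromosomes = 2, seed = 9)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  expect_identical(simulate_variants(cfg), simulate_variants(cfg))
  expect_identical(simulate_clonotypes(cfg), simulate_clonotypes(cfg))
  cfg2 <- simulation_config(n_ref_cells = 20, n_tumor_cells = 20, n_genes = 80,
                            n_chromosomes = 2, seed = 10)
  expect_false(identical(as.matrix(s1$matrix$counts),
                         as.matrix(simulate_counts(cfg2)$matrix$counts)))
})

test_that("planted fold change appears in the observed tumor/reference mean ratio", {
  cfg <- simulation_config(n_ref_cells = 400, n_tumor_cells = 400, n_genes = 200,
                           n_chromosomes = 2, dropout_rate = 0,
                           cnv_segments = list(list(chromosome = 1, start = 1,
                                                    end = 100, fold_change = 2)),
                           seed = 21)
  sim <- simulate_counts(cfg)
  counts <- as.matrix(sim$matrix$counts)
  tum <- sim$truth$cell_labels$label == "tumor"
  seg_genes <- names(sim$truth$gene_fold)[sim$truth$gene_fold == 2]
  ratio <- mean(counts[tum, seg_genes]) / mean(counts[!tum, seg_genes])
  # Monte-Carlo: 400 cells x 100 genes per arm keeps the ratio tight
  expect_gt(ratio, 1.85)
  expect_lt(ratio, 2.15)
  off_genes <- names(sim$truth$gene_fold)[sim$truth$gene_fold == 1]
  ratio_off <- mean(counts[tum, off_genes]) / mean(counts[!tum, off_genes])
  expect_gt(ratio_off, 0.95)
  expect_lt(ratio_off, 1.05)
})

test_that("null simulation draws tumor and reference cells from one distribution", {
  cfg <- simulation_config(n_ref_cells = 200, n_tumor_cells = 200, n_genes = 100,
                           n_chromosomes = 2, cnv_segments = list(), seed = 5)
  sim <- simulate_counts(cfg)
  counts <- as.matrix(sim$matrix$counts)
  tum <- sim$truth$cell_labels$label == "tumor"
  p <- stats::t.test(rowSums(counts[tum, ]), rowSums(counts[!tum, ]))$p.value
  expect_gt(p, 0.01)
})

test_that("mitochondrial fraction is controlled by the configured range", {
  cfg <- simulation_config(n_ref_cells = 200, n_tumor_cells = 0, n_genes = 200,
                           n_chromosomes = 2, mito_fraction_range = c(0.3, 0.4),
                           dropout_rate = 0, seed = 8)
  sim <- simulate_counts(cfg)
  qc <- suppressWarnings(compute_cell_qc(sim$matrix, min_umi = 0, min_genes = 0))
  expect_gt(mean(qc$mito_fraction), 0.28)
  expect_lt(mean(qc$mito_fraction), 0.42)
})

test_that("variant sharing follows the configured fraction", {
  site_key <- function(v, s) {
    r <- v[v$sample == s, ]
    paste(r$chromosome, r$position, r$ref, r$alt, sep = ":")
  }
  cfg1 <- simulation_config(n_lesions = 2, n_variants = 60,
                            shared_variant_fraction = 1, seed = 4)
  v1 <- simulate_variants(cfg1)
  expect_setequal(site_key(v1, "lesion_1"), site_key(v1, "lesion_2"))

  cfg0 <- simulation_config(n_lesions = 2, n_variants = 60,
                            shared_variant_fraction = 0, seed = 4)
  v0 <- simulate_variants(cfg0)
  expect_length(intersect(site_key(v0, "lesion_1"), site_key(v0, "lesion_2")), 0)

  cfg5 <- simulation_config(n_lesions = 2, n_variants = 100,
                            shared_variant_fraction = 0.5, seed = 4)
  v5 <- simulate_variants(cfg5)
  shared <- length(intersect(site_key(v5, "lesion_1"), site_key(v5, "lesion_2")))
  expect_equal(shared, 50)
  # depths respect alt <= total
  expect_true(all(v5$alt_depth <= v5$total_depth))
  expect_true(all(v5$alt_depth >= 0))
})

test_that("clonotype sharing controls pairwise repertoire overlap", {
  sets <- function(tbl) {
    split(unique(tbl[, c("sample", "clonotype_id")])$clonotype_id,
          unique(tbl[, c("sample", "clonotype_id")])$sample)
  }
  cfg0 <- simulation_config(n_repertoire_samples = 2, n_clones = 50,
                            clonotype_sharing = 0, seed = 6)
  s0 <- sets(simulate_clonotypes(cfg0))
  expect_equal(overlap_coefficient(s0[[1]], s0[[2]]), 0)

  cfg1 <- simulation_config(n_repertoire_samples = 2, n_clones = 50,
                            clonotype_sharing = 1, seed = 6)
  s1 <- sets(simulate_clonotypes(cfg1))
  expect_equal(overlap_coefficient(s1[[1]], s1[[2]]), 1)

  cfg3 <- simulation_config(n_repertoire_samples = 3, n_clones = 100,
                            clonotype_sharing = 0.3, seed = 6)
  s3 <- sets(simulate_clonotypes(cfg3))
  ov <- c(overlap_coefficient(s3[[1]], s3[[2]]),
          overlap_coefficient(s3[[1]], s3[[3]]),
          overlap_coefficient(s3[[2]], s3[[3]]))
  expect_true(all(abs(ov - 0.3) < 0.05))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(dropout_rate = 1.5), "dropout_rate")
  expect_error(simulation_config(mito_fraction_range = c(0.5, 0.2)), "mito")
  expect_error(simulation_config(
    cnv_segments = list(list(chromosome = 1, start = 1, end = 10,
                             fold_change = -2))), "fold_change")
  expect_error(simulation_config(n_genes = 5, n_chromosomes = 10), "n_genes")
})
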