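# Small programmatic fixtures shared across test files.

# dense toy counts matrix with named cells/genes
toy_counts <- function(n_cells, n_genes, seed = 1, lambda = 5) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes,
                dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                sprintf("g%03d", seq_len(n_genes))))
    m
  })
}

# brute-force centred moving average with truncated windows (O(G * w))
oracle_moving_average <- function(v, w) {
  half <- (w - 1) / 2
  vapply(seq_along(v), function(i) {
    lo <- max(1, i - half)
    hi <- min(length(v), i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

# brute-force Pearson correlation from first principles
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small simulated dataset reused by several CNV tests: a detectable
# operating point (few large chromosomes, two planted events)
small_cnv_sim <- function(seed = 42) {
  cfg <- simulation_config(
    n_ref_cells = 100, n_tumor_cells = 100, n_genes = 1000,
    n_chromosomes = 10,
    cnv_segments = list(
      list(chromosome = 1, start = 1, end = 100, fold_change = 2),
      list(chromosome = 2, start = 1, end = 100, fold_change = 0.5)),
    seed = seed)
  simulate_counts(cfg)
}
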