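#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list, so that a single object (and its single `seed`) determines all
#' simulated inputs. Defaults describe a small but realistic droplet-based
#' experiment: ~10k UMIs per cell, negative-binomial counts with moderate
#' overdispersion, a few percent mitochondrial content, and light dropout.
#'
#' @param n_ref_cells,n_tumor_cells Number of reference (normal epithelial)
#'   and tumour cells.
#' @param n_genes Number of annotated (nuclear) genes. The simulated matrix
#'   additionally carries `n_mito_genes` mitochondrial pseudo-genes named
#'   with `MT-`, so its gene dimension is `n_genes + n_mito_genes`.
#' @param n_chromosomes Number of chromosomes genes are spread over.
#' @param cnv_segments List of planted copy-number segments, each a list with
#'   `chromosome` (name or index), `start`, `end` (1-based gene indices
#'   within that chromosome, inclusive) and `fold_change` (> 0; 2 is a
#'   one-copy gain, 0.5 a one-copy loss). Empty list = null simulation.
#' @param mean_library_size Expected UMIs per cell.
#' @param dispersion Negative-binomial size parameter (inverse
#'   overdispersion); larger is closer to Poisson.
#' @param mito_fraction_range Length-2 vector; each cell's expected
#'   mitochondrial UMI fraction is drawn uniformly from this interval.
#' @param dropout_rate Probability that an observed count is zeroed by a
#'   post-hoc Bernoulli dropout mask.
#' @param n_mito_genes Number of `MT-` pseudo-genes.
#' @param n_lesions Number of tumour lesions for the variant simulator.
#' @param n_variants Variants per lesion (and size of the shared pool).
#' @param shared_variant_fraction Fraction of each lesion's variants drawn
#'   from the common pool; the rest are private.
#' @param n_repertoire_samples Number of samples for the clonotype simulator.
#' @param n_clones Clonotypes per sample.
#' @param clonotype_sharing Fraction of each sample's clonotypes that belong
#'   to a common shared set; pairwise overlap coefficients recover this value.
#' @param seed Integer seed; identical configs reproduce identical outputs.
#' @return A validated list of class `mplc_sim_config`.
#' @examples
#' cfg <- simulation_config(n_ref_cells = 50, n_tumor_cells = 50,
#'                          n_genes = 200, n_chromosomes = 4, seed = 1)
#' @export
simulation_config <- function(n_ref_cells = 200,
                              n_tumor_cells = 200,
                              n_genes = 2000,
                              n_chromosomes = 22,
                              cnv_segments = list(),
                              mean_library_size = 10000,
                              dispersion = 2,
                              mito_fraction_range = c(0.02, 0.12),
                              dropout_rate = 0.1,
                              n_mito_genes = 10,
                              n_lesions = 2,
                              n_variants = 100,
                              shared_variant_fraction = 0.3,
                              n_repertoire_samples = 3,
                              n_clones = 100,
                              clonotype_sharing = 0.2,
                              seed = 1L) {
  assert_count(n_ref_cells, "n_ref_cells")
  assert_count(n_tumor_cells, "n_tumor_cells", min = 0L)
  assert_count(n_genes, "n_genes")
  assert_count(n_chromosomes, "n_chromosomes")
  assert_count(n_mito_genes, "n_mito_genes", min = 0L)
  assert_scalar_number(mean_library_size, "mean_library_size", min = 1)
  assert_scalar_number(dispersion, "dispersion", min = 1e-6)
  assert_scalar_number(dropout_rate, "dropout_rate", min = 0, max = 1)
  assert_scalar_number(shared_variant_fraction, "shared_variant_fraction", 0, 1)
  assert_scalar_number(clonotype_sharing, "clonotype_sharing", 0, 1)
  assert_count(n_lesions, "n_lesions")
  assert_count(n_variants, "n_variants")
  assert_count(n_repertoire_samples, "n_repertoire_samples")
  assert_count(n_clones, "n_clones")
  if (length(mito_fraction_range) != 2 || any(mito_fraction_range < 0) ||
      any(mito_fraction_range > 1) || diff(mito_fraction_range) < 0) {
    abort("`mito_fraction_range` must be an increasing pair within [0, 1].")
  }
  if (n_genes < n_chromosomes) abort("`n_genes` must be >= `n_chromosomes`.")
  for (seg in cnv_segments) {
    if (!all(c("chromosome", "start", "end", "fold_change") %in% names(seg))) {
      abort("Each cnv_segment needs chromosome, start, end and fold_change.")
    }
    if (seg$fold_change <= 0) abort("`fold_change` must be > 0.")
    if (seg$start < 1 || seg$end < seg$start) {
      abort("Segment gene indices must satisfy 1 <= start <= end.")
    }
  }
  structure(
    list(n_ref_cells = as.integer(n_ref_cells),
         n_tumor_cells = as.integer(n_tumor_cells),
         n_genes = as.integer(n_genes),
         n_chromosomes = as.integer(n_chromosomes),
         cnv_segments = cnv_segments,
         mean_library_size = mean_library_size,
         dispersion = dispersion,
         mito_fraction_range = mito_fraction_range,
         dropout_rate = dropout_rate,
         n_mito_genes = as.integer(n_mito_genes),
         n_lesions = as.integer(n_lesions),
         n_variants = as.integer(n_variants),
         shared_variant_fraction = shared_variant_fraction,
         n_repertoire_samples = as.integer(n_repertoire_samples),
         n_clones = as.integer(n_clones),
         clonotype_sharing = clonotype_sharing,
         seed = as.integer(seed)),
    class = "mplc_sim_config")
}

#' Generate a deterministic gene annotation
#'
#' Spreads `n_genes` as evenly as possible over `n_chromosomes` (any
#' remainder goes to the earliest chromosomes), with strictly increasing
#' start coordinates within each chromosome and stable gene names
#' (`gene0001`, ...). No randomness is involved.
#'
#' @param n_genes,n_chromosomes Positive integers, `n_genes >= n_chromosomes`.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   ordered by genome position.
#' @examples
#' generate_gene_annotation(10, 2)
#' @export
generate_gene_annotation <- function(n_genes, n_chromosomes) {
  assert_count(n_genes, "n_genes")
  assert_count(n_chromosomes, "n_chromosomes")
  if (n_genes < n_chromosomes) abort("`n_genes` must be >= `n_chromosomes`.")
  base <- n_genes %/% n_chromosomes
  sizes <- rep(base, n_chromosomes) +
    rep(c(1L, 0L), c(n_genes %% n_chromosomes,
                     n_chromosomes - n_genes %% n_chromosomes))
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), sizes)
  within <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  width <- 10000L
  gap <- 90000L
  start <- (within - 1L) * (width + gap) + 1L
  tibble(
    gene_id = sprintf("gene%0*d", max(4L, nchar(n_genes)), seq_len(n_genes)),
    chromosome = chrom,
    start = start,
    end = start + width - 1L
  )
}

# Per-gene fold-change vector implied by the planted segments, over the
# annotation's gene order. Segments may address chromosomes by name or index.
segment_fold_vector <- function(annotation, cnv_segments) {
  fold <- setNames(rep(1, nrow(annotation)), annotation$gene_id)
  for (seg in cnv_segments) {
    chrom <- seg$chromosome
    if (is.numeric(chrom)) chrom <- paste0("chr", chrom)
    idx <- which(annotation$chromosome == chrom)
    if (!length(idx)) abort(sprintf("Segment chromosome '%s' not in annotation.", chrom))
    if (seg$end > length(idx)) {
      abort(sprintf("Segment end %d exceeds the %d genes on %s.",
                    seg$end, length(idx), chrom))
    }
    fold[idx[seg$start:seg$end]] <- seg$fold_change
  }
  fold
}

#' Simulate a single-cell count matrix with planted copy-number segments
#'
#' Draws counts from a Gamma-Poisson (negative-binomial) model with
#' log-normal per-gene base abundances. Reference and tumour cells share the
#' same base abundances; inside each planted segment the tumour-cell gene
#' means are multiplied by the segment's `fold_change`, which is the
#' expression footprint a DNA copy-number change leaves in scRNA-seq.
#' A block of `MT-` pseudo-genes gives each cell a controllable
#' mitochondrial fraction, and an independent Bernoulli dropout mask adds
#' extra sparsity. All randomness flows from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param annotation Gene annotation from [generate_gene_annotation()];
#'   generated from the config when `NULL`.
#' @return A list with `matrix` (an [expression_matrix()]; tumour cells carry
#'   `pathology_group = "IAC"`, reference cells `"normal"`) and `truth`, a
#'   list with `cell_labels` (tibble: cell_id, label in reference/tumor),
#'   `gene_fold` (named per-gene fold vector tumour cells carry) and
#'   `annotation`.
#' @examples
#' cfg <- simulation_config(n_ref_cells = 20, n_tumor_cells = 20,
#'                          n_genes = 100, n_chromosomes = 2, seed = 7)
#' sim <- simulate_counts(cfg)
#' dim(sim$matrix)
#' @export
simulate_counts <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "mplc_sim_config"))
  annotation <- annotation %||%
    generate_gene_annotation(config$n_genes, config$n_chromosomes)
  withr::with_seed(config$seed, {
    n_cells <- config$n_ref_cells + config$n_tumor_cells
    n_nuc <- nrow(annotation)
    n_mito <- config$n_mito_genes

    # relative abundances: log-normal weights, normalised to proportions
    w_nuc <- rlnorm(n_nuc, meanlog = 0, sdlog = 1)
    p_nuc <- w_nuc / sum(w_nuc)
    w_mito <- if (n_mito > 0) rlnorm(n_mito, 0, 0.5) else numeric(0)
    p_mito <- if (n_mito > 0) w_mito / sum(w_mito) else numeric(0)

    libs <- rlnorm(n_cells, meanlog = log(config$mean_library_size) - 0.25^2 / 2,
                   sdlog = 0.25)
    mito_f <- runif(n_cells, config$mito_fraction_range[1],
                    config$mito_fraction_range[2])

    fold <- segment_fold_vector(annotation, config$cnv_segments)
    is_tumor <- rep(c(FALSE, TRUE), c(config$n_ref_cells, config$n_tumor_cells))

    # expected counts: lib * (1 - mito) * p_g, times fold in tumour cells;
    # fold multiplies the mean directly (no renormalisation), so the
    # tumour/reference mean ratio over segment genes equals fold_change
    mu_nuc <- outer(libs * (1 - mito_f), p_nuc)
    mu_nuc[is_tumor, ] <- sweep(mu_nuc[is_tumor, , drop = FALSE], 2, fold, `*`)
    counts <- matrix(
      rnbinom(length(mu_nuc), mu = as.numeric(mu_nuc), size = config$dispersion),
      nrow = n_cells)
    if (n_mito > 0) {
      mu_m <- outer(libs * mito_f, p_mito)
      counts_m <- matrix(
        rnbinom(length(mu_m), mu = as.numeric(mu_m), size = config$dispersion),
        nrow = n_cells)
      counts <- cbind(counts, counts_m)
    }
    if (config$dropout_rate > 0) {
      keep <- matrix(rbinom(length(counts), 1, 1 - config$dropout_rate),
                     nrow = n_cells)
      counts <- counts * keep
    }
    cell_ids <- sprintf("cell%0*d", max(4L, nchar(n_cells)), seq_len(n_cells))
    gene_ids <- c(annotation$gene_id,
                  if (n_mito > 0) paste0("MT-", seq_len(n_mito)))
    dimnames(counts) <- list(cell_ids, gene_ids)

    meta <- tibble(
      cell_id = cell_ids,
      sample = ifelse(is_tumor, "tumor_1", "normal_1"),
      patient = "patient_1",
      pathology_group = ifelse(is_tumor, "IAC", "normal"),
      cell_type = "epithelial"
    )
    truth <- list(
      cell_labels = tibble(cell_id = cell_ids,
                           label = ifelse(is_tumor, "tumor", "reference")),
      gene_fold = fold,
      annotation = annotation
    )
    list(matrix = expression_matrix(counts, meta), truth = truth)
  })
}

#' Simulate per-lesion variant tables with controllable sharing
#'
#' Builds a common pool of `n_variants` candidate somatic variants; each
#' lesion receives `round(shared_variant_fraction * n_variants)` sites from
#' the pool (the same subset for every lesion) plus private sites of its
#' own, emulating the mostly-private mutation structure of independent
#' primary lesions. Effect classes are sampled as nonsynonymous SNV,
#' synonymous SNV or indel; depths are Poisson with a Beta-distributed true
#' allele fraction, so `alt_depth <= total_depth` always holds.
#'
#' @param config A [simulation_config()].
#' @return A tibble of variant records: `sample`, `patient`, `chromosome`,
#'   `position`, `ref`, `alt`, `gene`, `effect`, `alt_depth`, `total_depth`.
#' @examples
#' cfg <- simulation_config(n_lesions = 3, n_variants = 50,
#'                          shared_variant_fraction = 0.5, seed = 3)
#' simulate_variants(cfg)
#' @export
simulate_variants <- function(config) {
  stopifnot(inherits(config, "mplc_sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_variants
    f <- config$shared_variant_fraction
    n_shared <- round(f * n)
    bases <- c("A", "C", "G", "T")
    make_sites <- function(k, tag) {
      chrom <- paste0("chr", sample.int(config$n_chromosomes, k, replace = TRUE))
      pos <- sample.int(2e8, k)
      ref <- sample(bases, k, replace = TRUE)
      effect <- sample(c("nonsynonymous_snv", "synonymous_snv", "indel"),
                       k, replace = TRUE, prob = c(0.6, 0.25, 0.15))
      alt <- vapply(seq_len(k), function(i) {
        if (effect[i] == "indel") {
          paste0(ref[i], paste(sample(bases, 2, replace = TRUE), collapse = ""))
        } else {
          sample(setdiff(bases, ref[i]), 1)
        }
      }, character(1))
      tibble(site_id = paste0(tag, seq_len(k)), chromosome = chrom,
             position = pos, ref = ref, alt = alt,
             gene = paste0("gene", sample.int(max(200L, config$n_genes), k)),
             effect = effect)
    }
    shared_sites <- make_sites(n_shared, "shared_")
    lesions <- lapply(seq_len(config$n_lesions), function(l) {
      private <- make_sites(n - n_shared, sprintf("lesion%d_private_", l))
      sites <- bind_rows(shared_sites, private)
      m <- nrow(sites)
      total <- rpois(m, 150) + 20L
      vaf_true <- stats::rbeta(m, 2, 5)
      sites %>%
        mutate(sample = sprintf("lesion_%d", l),
               patient = "patient_1",
               total_depth = total,
               alt_depth = rbinom(m, total, vaf_true))
    })
    bind_rows(lesions) %>%
      select("sample", "patient", "chromosome", "position", "ref", "alt",
             "gene", "effect", "alt_depth", "total_depth", "site_id")
  })
}

#' Simulate clonotype tables with controllable repertoire sharing
#'
#' Each sample receives `n_clones` clonotypes: a shared block of
#' `round(clonotype_sharing * n_clones)` clonotypes common to every sample,
#' plus private clonotypes, so the pairwise overlap coefficient between
#' samples recovers `clonotype_sharing` (up to rounding). Clone sizes follow
#' a Zipf-like rank^-1 law; every cell carries a paired TRA and TRB chain
#' whose CDR3 amino-acid strings define the clonotype.
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `barcode`, `sample`, `chain`, `v_gene`,
#'   `cdr3_aa`, `umis`, `clonotype_id` (the planted truth).
#' @examples
#' cfg <- simulation_config(n_repertoire_samples = 2, n_clones = 20,
#'                          clonotype_sharing = 0.5, seed = 11)
#' simulate_clonotypes(cfg)
#' @export
simulate_clonotypes <- function(config) {
  stopifnot(inherits(config, "mplc_sim_config"))
  withr::with_seed(config$seed + 2L, {
    n <- config$n_clones
    n_shared <- round(config$clonotype_sharing * n)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    rand_cdr3 <- function(k, prefix) {
      vapply(seq_len(k), function(i) {
        paste0(prefix, paste(sample(aa, 9, replace = TRUE), collapse = ""), "F")
      }, character(1))
    }
    make_pool <- function(k, tag) {
      tibble(clonotype_id = paste0(tag, seq_len(k)),
             cdr3_trb = rand_cdr3(k, "CASS"),
             cdr3_tra = rand_cdr3(k, "CAV"),
             v_trb = paste0("TRBV", sample.int(30, k, replace = TRUE)),
             v_tra = paste0("TRAV", sample.int(40, k, replace = TRUE)))
    }
    shared_pool <- make_pool(n_shared, "shared_ct_")
    rows <- lapply(seq_len(config$n_repertoire_samples), function(s) {
      private <- make_pool(n - n_shared, sprintf("s%d_ct_", s))
      clones <- bind_rows(shared_pool, private)
      sizes <- pmax(1L, round(n / seq_len(n)))   # rank^-1 clone sizes
      clones <- clones[sample.int(n), ]           # random rank assignment
      clones$size <- sizes
      cells <- clones[rep(seq_len(n), clones$size), ]
      cells$barcode <- sprintf("S%d_bc%05d", s, seq_len(nrow(cells)))
      cells$sample <- sprintf("sample_%d", s)
      bind_rows(
        tibble(barcode = cells$barcode, sample = cells$sample, chain = "TRB",
               v_gene = cells$v_trb, cdr3_aa = cells$cdr3_trb,
               umis = rpois(nrow(cells), 4) + 1L,
               clonotype_id = cells$clonotype_id),
        tibble(barcode = cells$barcode, sample = cells$sample, chain = "TRA",
               v_gene = cells$v_tra, cdr3_aa = cells$cdr3_tra,
               umis = rpois(nrow(cells), 3) + 1L,
               clonotype_id = cells$clonotype_id)
      )
    })
    bind_rows(rows) %>% arrange(.data$sample, .data$barcode, .data$chain)
  })
}
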