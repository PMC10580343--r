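#' Default pipeline configuration
#'
#' Returns the full configuration list the pipeline understands, with every
#' stage parameter at its documented default. Supply a named list (or a
#' YAML file parsed to one) to [run_pipeline()] to override any subset.
#'
#' @return Named list of configuration entries.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "mplc_output",
    stages = list(simulate = TRUE, qc = TRUE, cnv = TRUE, composition = TRUE,
                  variants = TRUE, clonotypes = TRUE, interactions = TRUE),
    inputs = list(matrix_dir = NULL, annotation = NULL, variants = NULL,
                  clonotypes = NULL, lr_pairs = NULL),
    simulate = list(n_ref_cells = 200, n_tumor_cells = 200, n_genes = 2000,
                    n_chromosomes = 22,
                    cnv_segments = list(
                      list(chromosome = 1, start = 1, end = 90, fold_change = 2),
                      list(chromosome = 2, start = 1, end = 90, fold_change = 0.5)),
                    shared_variant_fraction = 0.3, clonotype_sharing = 0.2),
    qc = list(min_umi = 500, max_mito = 0.25, min_genes = 200,
              max_genes = 5000, min_expressing_fraction = 0.001,
              n_hvg = 2000, mito_gene_prefix = "MT-"),
    cnv = list(window_size = 101, clip = 3, top_fraction = 0.05,
               r_threshold = 0.4, s_threshold = 0.03),
    variants = list(exome_mb = 40, site_policy = "union_zero_fill"),
    clonotypes = list(key_mode = "paired_cdr3", group_by = "sample"),
    interactions = list(n_perm = 1000, alpha = 0.05, min_fraction = 0.30)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

log_stage <- function(lines, msg, log_path) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  line <- sprintf("[%s] %s", stamp, msg)
  inform(line)
  c(lines, line)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (`simulate` or input
#' loading, then `qc` -> `cnv` -> `composition`; `variants`, `clonotypes`
#' and `interactions` are independent), writes every stage output as TSV
#' under `outdir`, and returns a manifest of produced files with MD5
#' checksums. All randomness derives from the single `seed`, so a rerun
#' with the same configuration yields checksum-identical deterministic
#' outputs.
#'
#' @param config Named list overriding [default_pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @return Tibble manifest of class `mplc_manifest`: `stage`, `file`,
#'   `md5`. A `run_log.txt` with parameters, stage timings and the seed is
#'   written alongside the outputs (and listed in the manifest without a
#'   checksum, as it carries timestamps).
#' @examples
#' \donttest{
#' cfg <- list(outdir = tempfile(), simulate = list(n_genes = 300,
#'             n_chromosomes = 3, n_ref_cells = 50, n_tumor_cells = 50,
#'             cnv_segments = list(list(chromosome = 1, start = 1, end = 100,
#'                                      fold_change = 2))),
#'             cnv = list(window_size = 51),
#'             interactions = list(n_perm = 100))
#' manifest <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  manifest <- list()
  add_file <- function(stage, path) {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)))
  }
  log_lines <- log_stage(log_lines, sprintf("pipeline start (seed = %d)", cfg$seed),
                         NULL)
  log_lines <- c(log_lines, paste0("config: ", yaml::as.yaml(
    cfg[c("seed", "qc", "cnv", "variants", "clonotypes", "interactions")])))

  sim <- NULL
  truth <- NULL
  failed <- character(0)
  run_stage <- function(name, deps, fn) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible(NULL))
    if (any(deps %in% failed)) {
      log_lines <<- log_stage(log_lines, sprintf(
        "stage %s skipped: dependency failed (%s)", name,
        paste(intersect(deps, failed), collapse = ", ")), NULL)
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    ok <- tryCatch({fn(); TRUE}, error = function(e) {
      log_lines <<- log_stage(log_lines, sprintf("stage %s FAILED: %s",
                                                 name, conditionMessage(e)), NULL)
      FALSE
    })
    if (!ok) failed <<- c(failed, name) else {
      log_lines <<- log_stage(log_lines, sprintf(
        "stage %s done (%.1fs)", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs"))), NULL)
    }
    invisible(NULL)
  }

  matrix_obj <- NULL
  annotation <- NULL
  variant_tbl <- NULL
  contig_tbl <- NULL

  run_stage("simulate", character(0), function() {
    sim_args <- cfg$simulate
    sim_args$seed <- NULL
    sim_cfg <- do.call(simulation_config, c(sim_args, list(seed = cfg$seed)))
    sim <- simulate_counts(sim_cfg)
    matrix_obj <<- sim$matrix
    annotation <<- sim$truth$annotation
    truth <<- sim$truth
    variant_tbl <<- simulate_variants(sim_cfg)
    contig_tbl <<- simulate_clonotypes(sim_cfg)
    write_matrix_dir(sim$matrix, file.path(outdir, "matrix"))
    for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv", "cell_meta.tsv")) {
      add_file("simulate", file.path(outdir, "matrix", f))
    }
    readr::write_tsv(annotation, file.path(outdir, "annotation.tsv"))
    add_file("simulate", file.path(outdir, "annotation.tsv"))
    readr::write_tsv(truth$cell_labels, file.path(outdir, "truth_cell_labels.tsv"))
    add_file("simulate", file.path(outdir, "truth_cell_labels.tsv"))
    readr::write_tsv(variant_tbl, file.path(outdir, "variants.tsv"))
    add_file("simulate", file.path(outdir, "variants.tsv"))
    readr::write_tsv(contig_tbl, file.path(outdir, "clonotype_contigs.tsv"))
    add_file("simulate", file.path(outdir, "clonotype_contigs.tsv"))
  })

  if (!isTRUE(cfg$stages$simulate)) {
    if (!is.null(cfg$inputs$matrix_dir)) {
      matrix_obj <- read_matrix_dir(cfg$inputs$matrix_dir)
    }
    if (!is.null(cfg$inputs$annotation)) {
      annotation <- read_gene_annotation(cfg$inputs$annotation)
    }
    if (!is.null(cfg$inputs$variants)) {
      variant_tbl <- read_variants(cfg$inputs$variants)
    }
    if (!is.null(cfg$inputs$clonotypes)) {
      contig_tbl <- read_clonotypes(cfg$inputs$clonotypes)
    }
  }

  qc_matrix <- NULL
  run_stage("qc", "simulate", function() {
    if (is.null(matrix_obj)) abort("qc: no expression matrix available.")
    qc <- compute_cell_qc(matrix_obj,
                          mito_gene_prefix = cfg$qc$mito_gene_prefix,
                          min_umi = cfg$qc$min_umi, max_mito = cfg$qc$max_mito,
                          min_genes = cfg$qc$min_genes,
                          max_genes = cfg$qc$max_genes)
    readr::write_tsv(tidy(qc), file.path(outdir, "qc_report.tsv"))
    add_file("qc", file.path(outdir, "qc_report.tsv"))
    filtered <- filter_cells(matrix_obj, qc)
    filtered <- filter_genes(filtered, cfg$qc$min_expressing_fraction)
    hvg <- select_hvg(filtered, min(cfg$qc$n_hvg, ncol(filtered$counts)))
    writeLines(hvg, file.path(outdir, "hvg.txt"))
    add_file("qc", file.path(outdir, "hvg.txt"))
    qc_matrix <<- filtered
  })

  run_stage("cnv", c("simulate", "qc"), function() {
    m <- qc_matrix %||% matrix_obj
    if (is.null(m) || is.null(annotation)) {
      abort("cnv: matrix and annotation are required.")
    }
    meta <- m$cell_meta
    refs <- meta$cell_id[meta$pathology_group == "normal"]
    cnv <- compute_cnv_matrix(m, annotation, refs,
                              window_size = cfg$cnv$window_size,
                              clip = cfg$cnv$clip)
    groups <- setNames(meta$sample, meta$cell_id)
    scores <- compute_r_score(cnv, groups, top_fraction = cfg$cnv$top_fraction)
    calls <- classify_malignancy(scores,
                                 r_threshold = cfg$cnv$r_threshold,
                                 s_threshold = cfg$cnv$s_threshold)
    readr::write_tsv(tidy(calls), file.path(outdir, "malignancy_calls.tsv"))
    add_file("cnv", file.path(outdir, "malignancy_calls.tsv"))
    readr::write_tsv(cnv$gene_order, file.path(outdir, "cnv_gene_order.tsv"))
    add_file("cnv", file.path(outdir, "cnv_gene_order.tsv"))
    # cell metadata gains the call for downstream composition
    matrix_obj$cell_meta <<- left_join(
      matrix_obj$cell_meta, tidy(calls)[, c("cell_id", "label")], by = "cell_id")
  })

  run_stage("composition", "simulate", function() {
    if (is.null(matrix_obj)) abort("composition: no cell metadata available.")
    meta <- matrix_obj$cell_meta
    comp <- composition(meta, group_col = "pathology_group")
    readr::write_tsv(comp$by_sample, file.path(outdir, "composition_by_sample.tsv"))
    add_file("composition", file.path(outdir, "composition_by_sample.tsv"))
    readr::write_tsv(comp$group_mean, file.path(outdir, "composition_group_mean.tsv"))
    add_file("composition", file.path(outdir, "composition_group_mean.tsv"))
  })

  run_stage("variants", "simulate", function() {
    if (is.null(variant_tbl)) abort("variants: no variant table available.")
    stats_tbl <- lesion_tmb(variant_tbl, cfg$variants$exome_mb * 1e6)
    readr::write_tsv(stats_tbl, file.path(outdir, "lesion_tmb.tsv"))
    add_file("variants", file.path(outdir, "lesion_tmb.tsv"))
    freq <- gene_mutation_frequency(variant_tbl, min_frequency = 0)
    readr::write_tsv(freq, file.path(outdir, "gene_mutation_frequency.tsv"))
    add_file("variants", file.path(outdir, "gene_mutation_frequency.tsv"))
    vc <- vaf_correlation_matrix(variant_tbl,
                                 site_policy = cfg$variants$site_policy)
    readr::write_tsv(as_tibble(vc, rownames = "sample"),
                     file.path(outdir, "vaf_correlation.tsv"))
    add_file("variants", file.path(outdir, "vaf_correlation.tsv"))
    spec <- substitution_spectrum(variant_tbl)
    readr::write_tsv(spec, file.path(outdir, "substitution_spectrum.tsv"))
    add_file("variants", file.path(outdir, "substitution_spectrum.tsv"))
  })

  run_stage("clonotypes", "simulate", function() {
    if (is.null(contig_tbl)) abort("clonotypes: no contig table available.")
    rep <- build_clonotypes(contig_tbl, key_mode = cfg$clonotypes$key_mode)
    readr::write_tsv(rep$clones, file.path(outdir, "clonotypes.tsv"))
    add_file("clonotypes", file.path(outdir, "clonotypes.tsv"))
    ov <- overlap_matrix(rep, group_by = cfg$clonotypes$group_by)
    readr::write_tsv(as_tibble(unclass(ov), rownames = "sample"),
                     file.path(outdir, "clonotype_overlap.tsv"))
    add_file("clonotypes", file.path(outdir, "clonotype_overlap.tsv"))
  })

  run_stage("interactions", "simulate", function() {
    m <- matrix_obj
    if (is.null(m)) abort("interactions: no expression matrix available.")
    pairs <- if (!is.null(cfg$inputs$lr_pairs)) {
      read_lr_pairs(cfg$inputs$lr_pairs)
    } else {
      demo_lr_pairs(genes = colnames(m$counts), seed = cfg$seed)
    }
    labels <- setNames(m$cell_meta$pathology_group, m$cell_meta$cell_id)
    res <- test_interactions(m, labels, pairs,
                             n_perm = cfg$interactions$n_perm,
                             min_fraction = cfg$interactions$min_fraction,
                             seed = cfg$seed)
    readr::write_tsv(tidy(res), file.path(outdir, "interactions.tsv"))
    add_file("interactions", file.path(outdir, "interactions.tsv"))
    net <- interaction_network(res, alpha = cfg$interactions$alpha)
    readr::write_tsv(net$edges, file.path(outdir, "interaction_edges.tsv"))
    add_file("interactions", file.path(outdir, "interaction_edges.tsv"))
  })

  log_path <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, log_path)
  out <- bind_rows(manifest)
  out <- bind_rows(out, tibble(stage = "log", file = "run_log.txt",
                               md5 = NA_character_))
  readr::write_tsv(out, file.path(outdir, "manifest.tsv"))
  if (length(failed)) {
    warn(paste0("Stages failed or skipped: ", paste(unique(failed), collapse = ", ")))
  }
  attr(out, "failed_stages") <- unique(failed)
  attr(out, "outdir") <- outdir
  class(out) <- c("mplc_manifest", class(out))
  out
}
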