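#' Variant allele frequency
#'
#' VAF = alt-supporting read depth over total read depth at a site.
#'
#' @param alt_depth,total_depth Non-negative integer vectors (recycled);
#'   `alt_depth <= total_depth` and `total_depth > 0` are required.
#' @return Numeric vector in \[0, 1\].
#' @examples
#' compute_vaf(30, 100)  # 0.3
#' @export
compute_vaf <- function(alt_depth, total_depth) {
  if (any(total_depth <= 0)) abort("VAF is undefined when `total_depth` is 0.")
  if (any(alt_depth < 0) || any(alt_depth > total_depth)) {
    abort("`alt_depth` must lie in [0, total_depth].")
  }
  alt_depth / total_depth
}

#' Tumour mutational burden of a variant set
#'
#' TMB = (number of nonsynonymous SNVs + number of indels) divided by the
#' exome length in megabases. The exome length is a required input — there
#' is no hidden default.
#'
#' @param records Variant tibble with an `effect` column using the classes
#'   `nonsynonymous_snv`, `synonymous_snv`, `indel`, `other`.
#' @param exome_length_bp Total exon length in base pairs (> 0).
#' @return One-row tibble: `n_nonsyn`, `n_indel`, `n_records`,
#'   `exome_length_bp`, `tmb` (mutations per Mb).
#' @examples
#' recs <- tibble::tibble(effect = rep(c("nonsynonymous_snv", "indel",
#'                                       "synonymous_snv"), c(30, 10, 5)))
#' compute_tmb(recs, 40e6)$tmb  # 1.0
#' @export
compute_tmb <- function(records, exome_length_bp) {
  assert_scalar_number(exome_length_bp, "exome_length_bp", min = 1e-9)
  records <- as_tibble(records)
  n_nonsyn <- sum(records$effect == "nonsynonymous_snv")
  n_indel <- sum(records$effect == "indel")
  tibble(
    n_nonsyn = n_nonsyn,
    n_indel = n_indel,
    n_records = nrow(records),
    exome_length_bp = exome_length_bp,
    tmb = (n_nonsyn + n_indel) / (exome_length_bp / 1e6)
  )
}

#' Per-lesion TMB table
#'
#' @param records Variant tibble with `sample` and `effect` columns.
#' @param exome_length_bp Exon length in bp shared by all lesions.
#' @return Tibble with one row per lesion (`sample`) and the
#'   [compute_tmb()] columns.
#' @export
lesion_tmb <- function(records, exome_length_bp) {
  records <- as_tibble(records)
  records %>%
    group_by(.data$sample) %>%
    dplyr::group_modify(~ compute_tmb(.x, exome_length_bp)) %>%
    ungroup()
}

#' Fraction of lesions mutated per gene
#'
#' For each gene, the fraction of lesions carrying at least one variant
#' record in that gene. The denominator is the supplied lesion list (so
#' lesions without any record still count), matching the per-region
#' convention of multi-lesion mutational landscapes.
#'
#' @param records Variant tibble with `sample` and `gene` columns.
#' @param lesions Character vector of lesion identifiers defining the
#'   denominator; defaults to the lesions present in `records`.
#' @param min_frequency Report only genes with frequency strictly greater
#'   than this (default 0.05); set to 0 to keep everything.
#' @return Tibble `gene`, `n_lesions_mutated`, `n_lesions`, `frequency`,
#'   sorted by decreasing frequency.
#' @examples
#' recs <- tibble::tibble(sample = c("l1", "l2", "l2"),
#'                        gene = c("EGFR", "EGFR", "RBM10"))
#' gene_mutation_frequency(recs, lesions = c("l1", "l2", "l3"),
#'                         min_frequency = 0)
#' @export
gene_mutation_frequency <- function(records, lesions = NULL, min_frequency = 0.05) {
  records <- as_tibble(records)
  lesions <- lesions %||% sort(unique(records$sample))
  if (!length(lesions)) abort("The lesion list is empty.")
  records %>%
    filter(.data$sample %in% lesions) %>%
    distinct(.data$gene, .data$sample) %>%
    count(.data$gene, name = "n_lesions_mutated") %>%
    mutate(n_lesions = length(lesions),
           frequency = .data$n_lesions_mutated / .data$n_lesions) %>%
    filter(.data$frequency > min_frequency) %>%
    arrange(dplyr::desc(.data$frequency), .data$gene)
}

#' VAF correlation between two lesions
#'
#' Pearson correlation of variant allele frequencies of two record sets
#' over a common site axis. Sites are keyed by
#' (chromosome, position, ref, alt). Under `"union_zero_fill"` (default)
#' the union of sites is used and a site absent from one lesion
#' contributes VAF 0 there — private mutations then actively push the
#' correlation down, which is the behaviour of interest when asking whether
#' two foci share an origin. Under `"shared_sites"` only sites present in
#' both lesions enter.
#'
#' @param records_a,records_b Variant tibbles with `chromosome`, `position`,
#'   `ref`, `alt`, `alt_depth`, `total_depth`.
#' @param site_policy `"union_zero_fill"` or `"shared_sites"`.
#' @return A single correlation in \[-1, 1\].
#' @export
vaf_correlation <- function(records_a, records_b,
                            site_policy = c("union_zero_fill", "shared_sites")) {
  site_policy <- match.arg(site_policy)
  key <- function(r) paste(r$chromosome, r$position, r$ref, r$alt, sep = ":")
  a <- as_tibble(records_a)
  b <- as_tibble(records_b)
  a_vaf <- setNames(compute_vaf(a$alt_depth, a$total_depth), key(a))
  b_vaf <- setNames(compute_vaf(b$alt_depth, b$total_depth), key(b))
  sites <- if (site_policy == "shared_sites") {
    intersect(names(a_vaf), names(b_vaf))
  } else {
    union(names(a_vaf), names(b_vaf))
  }
  if (length(sites) < 3) {
    abort(sprintf("Only %d usable site(s); at least 3 are required.", length(sites)))
  }
  va <- ifelse(sites %in% names(a_vaf), a_vaf[sites], 0)
  vb <- ifelse(sites %in% names(b_vaf), b_vaf[sites], 0)
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("VAF correlation is undefined for a constant VAF vector.")
  }
  cor(va, vb)
}

#' Pairwise VAF correlation matrix across lesions
#'
#' @param records Variant tibble with a `sample` column.
#' @param site_policy Passed to [vaf_correlation()].
#' @return Symmetric matrix of correlations (diagonal 1); undefined pairs
#'   are `NA` with a warning.
#' @export
vaf_correlation_matrix <- function(records,
                                   site_policy = c("union_zero_fill", "shared_sites")) {
  site_policy <- match.arg(site_policy)
  records <- as_tibble(records)
  lesions <- sort(unique(records$sample))
  m <- diag(1, length(lesions))
  dimnames(m) <- list(lesions, lesions)
  for (i in seq_along(lesions)) {
    for (j in seq_len(i - 1L)) {
      val <- tryCatch(
        vaf_correlation(records[records$sample == lesions[i], ],
                        records[records$sample == lesions[j], ],
                        site_policy = site_policy),
        error = function(e) {
          warn(sprintf("VAF correlation %s vs %s undefined: %s",
                       lesions[i], lesions[j], conditionMessage(e)))
          NA_real_
        })
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

#' Single-nucleotide substitution spectrum
#'
#' Tallies SNV records into the six pyrimidine-centred substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G); purine-reference records are complemented
#' first. Indels and multi-nucleotide records are ignored.
#'
#' @param records Variant tibble with `ref` and `alt` columns.
#' @return Tibble `substitution`, `n`, `fraction` over the six classes
#'   (fractions sum to 1 when any SNV is present).
#' @export
substitution_spectrum <- function(records) {
  records <- as_tibble(records)
  snv <- records[nchar(records$ref) == 1 & nchar(records$alt) == 1 &
                   records$ref != records$alt &
                   records$ref %in% c("A", "C", "G", "T") &
                   records$alt %in% c("A", "C", "G", "T"), ]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- snv$ref
  alt <- snv$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[snv$ref[flip]]
  alt[flip] <- comp[snv$alt[flip]]
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  obs <- paste0(ref, ">", alt)
  n <- vapply(classes, function(cl) sum(obs == cl), integer(1))
  tibble(substitution = classes, n = as.integer(n),
         fraction = if (sum(n) > 0) n / sum(n) else rep(0, 6))
}
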