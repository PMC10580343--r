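#' Collapse receptor chains into clonotypes and summarise repertoires
#'
#' Takes per-chain contig rows (one row per cell barcode, chain and CDR3)
#' and groups cells into clones by a configurable identity key:
#'
#' * `"paired_cdr3"` (default): the TRB and TRA CDR3 amino-acid strings
#'   joined as `"TRBCDR3-TRACDR3"` (heavy-light `IGH`/`IGK`/`IGL` pairing
#'   for BCR input). Cells with only one chain fall back to that chain's
#'   CDR3 and are flagged `single_chain`.
#' * `"cdr3_only"`: concatenation of the available CDR3s.
#' * `"v_cdr3"`: V gene and CDR3 joined per chain.
#'
#' When a barcode carries more than one contig of a chain, the highest-UMI
#' contig is kept (ties break by lexicographic CDR3).
#'
#' @param contigs Data frame with columns `barcode`, `sample`, `chain`
#'   (TRA/TRB/IGH/IGK/IGL), `v_gene`, `cdr3_aa`, optionally `umis`.
#' @param key_mode One of `"paired_cdr3"`, `"cdr3_only"`, `"v_cdr3"`.
#' @return An object of class `mplc_repertoire`: list with
#'   `cells` (tibble: barcode, sample, clonotype, single_chain),
#'   `clones` (tibble: sample, clonotype, n_cells, freq — frequencies sum
#'   to 1 within each sample), and `v_usage` (tibble: sample, chain,
#'   v_gene, n, freq).
#' @examples
#' tbl <- tibble::tibble(
#'   barcode = c("bc1", "bc1", "bc2", "bc2"), sample = "s1",
#'   chain = c("TRB", "TRA", "TRB", "TRA"),
#'   v_gene = c("TRBV2", "TRAV1", "TRBV2", "TRAV1"),
#'   cdr3_aa = c("CASSGLAAKPGELF", "CAVRRGQNFV",
#'               "CASSGLAAKPGELF", "CAVRRGQNFV"))
#' build_clonotypes(tbl)$clones
#' @export
build_clonotypes <- function(contigs, key_mode = c("paired_cdr3", "cdr3_only", "v_cdr3")) {
  key_mode <- match.arg(key_mode)
  contigs <- as_tibble(contigs)
  needed <- c("barcode", "sample", "chain", "v_gene", "cdr3_aa")
  missing_cols <- setdiff(needed, names(contigs))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  known <- c("TRA", "TRB", "IGH", "IGK", "IGL")
  bad <- which(!contigs$chain %in% known)
  if (length(bad)) {
    abort(sprintf("Unknown chain label(s) in rows: %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  if (!"umis" %in% names(contigs)) contigs$umis <- 1L

  # one dominant contig per (barcode, chain)
  dominant <- contigs %>%
    arrange(.data$barcode, .data$chain, dplyr::desc(.data$umis), .data$cdr3_aa) %>%
    distinct(.data$barcode, .data$chain, .keep_all = TRUE)

  # chain roles: primary = TRB or IGH; secondary = TRA or light chain
  dominant <- dominant %>%
    mutate(role = ifelse(.data$chain %in% c("TRB", "IGH"), "primary", "secondary"))

  per_cell <- dominant %>%
    group_by(.data$barcode, .data$sample) %>%
    summarise(
      primary_cdr3 = first(.data$cdr3_aa[.data$role == "primary"]) %||% NA_character_,
      secondary_cdr3 = first(.data$cdr3_aa[.data$role == "secondary"]) %||% NA_character_,
      primary_key = first(paste(.data$v_gene, .data$cdr3_aa, sep = ":")[.data$role == "primary"]) %||% NA_character_,
      secondary_key = first(paste(.data$v_gene, .data$cdr3_aa, sep = ":")[.data$role == "secondary"]) %||% NA_character_,
      .groups = "drop"
    )
  join2 <- function(a, b) {
    ifelse(!is.na(a) & !is.na(b), paste(a, b, sep = "-"),
           ifelse(!is.na(a), a, b))
  }
  per_cell <- per_cell %>%
    mutate(
      clonotype = switch(key_mode,
        paired_cdr3 = join2(.data$primary_cdr3, .data$secondary_cdr3),
        cdr3_only = join2(.data$primary_cdr3, .data$secondary_cdr3),
        v_cdr3 = join2(.data$primary_key, .data$secondary_key)),
      single_chain = is.na(.data$primary_cdr3) | is.na(.data$secondary_cdr3)
    ) %>%
    select("barcode", "sample", "clonotype", "single_chain")

  clones <- per_cell %>%
    count(.data$sample, .data$clonotype, name = "n_cells") %>%
    group_by(.data$sample) %>%
    mutate(freq = .data$n_cells / sum(.data$n_cells)) %>%
    ungroup() %>%
    arrange(.data$sample, dplyr::desc(.data$n_cells), .data$clonotype)

  v_usage <- dominant %>%
    count(.data$sample, .data$chain, .data$v_gene, name = "n") %>%
    group_by(.data$sample, .data$chain) %>%
    mutate(freq = .data$n / sum(.data$n)) %>%
    ungroup()

  structure(list(cells = per_cell, clones = clones, v_usage = v_usage),
            class = "mplc_repertoire")
}

#' @export
print.mplc_repertoire <- function(x, ...) {
  cat(sprintf("<mplc_repertoire> %d cells, %d samples, %d distinct clonotypes\n",
              nrow(x$cells), length(unique(x$clones$sample)),
              length(unique(x$clones$clonotype))))
  invisible(x)
}

# Accepts a character vector of clonotypes, a per-sample clone tibble, or an
# mplc_repertoire restricted to one sample.
clonotype_set <- function(rep) {
  if (is.character(rep)) return(unique(rep))
  if (inherits(rep, "mplc_repertoire")) return(unique(rep$clones$clonotype))
  if (is.data.frame(rep) && "clonotype" %in% names(rep)) {
    return(unique(rep$clonotype))
  }
  abort("Cannot interpret repertoire; supply clonotypes or a clone table.")
}

#' Overlap coefficient between two repertoires
#'
#' `|A intersect B| / min(|A|, |B|)` over unique clonotypes — 1 when the
#' smaller repertoire is entirely contained in the larger, 0 when disjoint.
#'
#' @param rep_a,rep_b Character vectors of clonotypes, clone tibbles with a
#'   `clonotype` column, or [build_clonotypes()] results.
#' @return A single number in \[0, 1\].
#' @examples
#' overlap_coefficient(c("a", "b", "c"), c("b", "c", "d", "e"))  # 2/3
#' @export
overlap_coefficient <- function(rep_a, rep_b) {
  a <- clonotype_set(rep_a)
  b <- clonotype_set(rep_b)
  if (!length(a) || !length(b)) abort("Overlap is undefined for an empty repertoire.")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Number of clonotypes shared by two repertoires
#'
#' @inheritParams overlap_coefficient
#' @return Integer count `|A intersect B|` over unique clonotypes.
#' @export
shared_clone_counts <- function(rep_a, rep_b) {
  length(intersect(clonotype_set(rep_a), clonotype_set(rep_b)))
}

#' Pairwise overlap-coefficient matrix
#'
#' @param rep A [build_clonotypes()] result, or a tibble with `clonotype`
#'   plus a grouping column.
#' @param group_by Name of the grouping column (default `"sample"`).
#' @return A symmetric numeric matrix of class `mplc_overlap` with unit
#'   diagonal; a pair with an empty side yields `NA` with a warning.
#' @export
overlap_matrix <- function(rep, group_by = "sample") {
  tbl <- if (inherits(rep, "mplc_repertoire")) rep$clones else as_tibble(rep)
  if (!all(c("clonotype", group_by) %in% names(tbl))) {
    abort(sprintf("Need columns `clonotype` and `%s`.", group_by))
  }
  groups <- sort(unique(tbl[[group_by]]))
  if (length(groups) < 2) abort("Need at least two groups for an overlap matrix.")
  sets <- lapply(groups, function(g) unique(tbl$clonotype[tbl[[group_by]] == g]))
  names(sets) <- groups
  m <- diag(1, length(groups))
  dimnames(m) <- list(groups, groups)
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      val <- tryCatch(overlap_coefficient(sets[[i]], sets[[j]]),
                      error = function(e) {
                        warn(sprintf("Overlap %s vs %s undefined: %s",
                                     groups[i], groups[j], conditionMessage(e)))
                        NA_real_
                      })
      m[i, j] <- m[j, i] <- val
    }
  }
  class(m) <- c("mplc_overlap", class(m))
  m
}
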