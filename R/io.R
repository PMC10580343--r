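#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (uncompressed)
#' in `dir`. Matrices are stored genes x cells on disk, as the 10x layout
#' does; the returned object is cells x genes. An optional `cell_meta.tsv`
#' in the same directory is attached as cell metadata.
#'
#' @param dir Directory path.
#' @return An [expression_matrix()].
#' @export
read_matrix_dir <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  if (!all(file.exists(paths))) {
    abort(sprintf("Expected matrix.mtx, barcodes.tsv, features.tsv under %s", dir))
  }
  m <- Matrix::readMM(paths[1])
  barcodes <- readr::read_tsv(paths[2], col_names = "cell_id",
                              show_col_types = FALSE)$cell_id
  features <- readr::read_tsv(paths[3], col_names = "gene_id",
                              show_col_types = FALSE)$gene_id
  if (nrow(m) != length(features) || ncol(m) != length(barcodes)) {
    abort("Matrix dimensions do not match the barcode/feature lists.")
  }
  counts <- Matrix::t(m)
  dimnames(counts) <- list(barcodes, features)
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE)
  } else NULL
  expression_matrix(counts, meta)
}

#' Write an expression matrix as a 10x-style MTX triplet
#'
#' @param x An [expression_matrix()].
#' @param dir Output directory (created if needed). Writes `matrix.mtx`
#'   (genes x cells), `barcodes.tsv`, `features.tsv` and `cell_meta.tsv`.
#' @return `dir`, invisibly.
#' @export
write_matrix_dir <- function(x, dir) {
  stopifnot(inherits(x, "mplc_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "features.tsv"))
  readr::write_tsv(x$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read a gene annotation table
#'
#' Tab-delimited with columns `gene_id`, `chromosome`, `start`, `end`
#' (header optional when exactly four columns).
#'
#' @param path File path.
#' @return Tibble with the four annotation columns.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  ann <- if (has_header) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_tsv(path, col_names = c("gene_id", "chromosome", "start", "end"),
                    show_col_types = FALSE)
  }
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(ann))) {
    abort("Annotation needs columns gene_id, chromosome, start, end.")
  }
  if (any(ann$start > ann$end)) abort("Annotation has start > end.")
  as_tibble(ann[, need])
}

#' Read a variant table (TSV or VCF)
#'
#' Tab-delimited tables must carry `sample`, `chromosome`, `position`,
#' `ref`, `alt`, `gene`, `effect`, `alt_depth`, `total_depth`. VCF 4.2
#' files (read through the vcfR package) must carry per-sample `AD` or
#' `DP`/`AO`-style depth fields plus `GENE` and `EFFECT` INFO keys; rows
#' without depths get `NA`.
#'
#' @param path File path; `.vcf` triggers VCF parsing.
#' @param sample Sample name to assign when the file has no sample column
#'   (default: file name without extension).
#' @return Variant tibble as used by [compute_tmb()] and friends.
#' @export
read_variants <- function(path, sample = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      abort("Reading VCF requires the vcfR package.")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[, 1],
                   error = function(e) rep(NA_character_, nrow(fix)))
    ad_split <- strsplit(ad %||% rep(NA_character_, nrow(fix)), ",")
    ref_d <- suppressWarnings(as.integer(vapply(ad_split, function(z) z[1] %||% NA_character_, character(1))))
    alt_d <- suppressWarnings(as.integer(vapply(ad_split, function(z) if (length(z) > 1) z[2] else NA_character_, character(1))))
    info_field <- function(key) {
      m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"), fix$INFO))
      out <- rep(NA_character_, nrow(fix))
      hit <- grepl(paste0(key, "="), fix$INFO)
      out[hit] <- sub(paste0(".*", key, "="), "", m)
      out
    }
    effect <- info_field("EFFECT")
    effect[is.na(effect)] <- "other"
    tibble(
      sample = sample %||% sub("\\.vcf(\\.gz)?$", "", basename(path)),
      chromosome = fix$CHROM,
      position = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      gene = info_field("GENE"),
      effect = effect,
      alt_depth = alt_d,
      total_depth = ref_d + alt_d
    )
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"sample" %in% names(tbl)) {
      tbl$sample <- sample %||% sub("\\.[^.]*$", "", basename(path))
    }
    need <- c("sample", "chromosome", "position", "ref", "alt", "gene",
              "effect", "alt_depth", "total_depth")
    missing_cols <- setdiff(need, names(tbl))
    if (length(missing_cols)) {
      abort(paste0("Variant table misses: ", paste(missing_cols, collapse = ", ")))
    }
    as_tibble(tbl)
  }
}

#' Write variants as a minimal VCF 4.2
#'
#' One file per call; depths go into the `AD` genotype field and
#' gene/effect into INFO. The inverse of the VCF branch of
#' [read_variants()].
#'
#' @param records Variant tibble (one sample).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(records, path) {
  records <- as_tibble(records)
  if (length(unique(records$sample)) > 1) {
    abort("Write one sample per VCF file.")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           unique(records$sample))
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;EFFECT=%s\tAD\t%d,%d",
                  records$chromosome, records$position, records$ref,
                  records$alt, records$gene, records$effect,
                  records$total_depth - records$alt_depth, records$alt_depth)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a clonotype contig table
#'
#' Accepts an AIRR-like TSV (`barcode`, `sample`, `chain`, `v_gene`,
#' `cdr3_aa`, optional `umis`) or a 10x `filtered_contig_annotations.csv`,
#' whose columns are remapped (`cdr3` -> `cdr3_aa`, `reads`/`umis` kept).
#'
#' @param path File path; `.csv` triggers the 10x column mapping.
#' @param sample Sample to assign when absent from the file.
#' @return Contig tibble suitable for [build_clonotypes()].
#' @export
read_clonotypes <- function(path, sample = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    tbl <- readr::read_csv(path, show_col_types = FALSE)
    map <- c(barcode = "barcode", chain = "chain", v_gene = "v_gene",
             cdr3_aa = "cdr3", umis = "umis")
    out <- tibble(
      barcode = tbl[[map["barcode"]]],
      chain = tbl[[map["chain"]]],
      v_gene = tbl[[map["v_gene"]]],
      cdr3_aa = tbl[[map["cdr3_aa"]]],
      umis = if ("umis" %in% names(tbl)) tbl$umis else 1L
    )
    out$sample <- if ("sample" %in% names(tbl)) tbl$sample else
      sample %||% sub("\\.[^.]*$", "", basename(path))
    out
  } else {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    if (!"sample" %in% names(tbl)) {
      tbl$sample <- sample %||% sub("\\.[^.]*$", "", basename(path))
    }
    as_tibble(tbl)
  }
}

#' Read a two-column ligand-receptor pair list
#'
#' @param path TSV with columns `ligand` and `receptor` (header optional
#'   when exactly two columns).
#' @return Tibble `ligand`, `receptor`, `pair_id`.
#' @export
read_lr_pairs <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("ligand", first, fixed = TRUE)
  tbl <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE)
  if (!has_header) names(tbl) <- c("ligand", "receptor")
  if (!all(c("ligand", "receptor") %in% names(tbl))) {
    abort("Pair list needs `ligand` and `receptor` columns.")
  }
  tbl <- as_tibble(tbl)
  if (!"pair_id" %in% names(tbl)) {
    tbl$pair_id <- paste(tbl$ligand, tbl$receptor, sep = "_")
  }
  if (anyDuplicated(tbl$pair_id)) abort("Pair ids must be unique.")
  tbl
}
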