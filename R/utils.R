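#' Natural ordering of chromosome names
#'
#' Orders `chr1..chr22, chrX, chrY, chrM` (with or without the `chr` prefix)
#' before any other contig, which falls back to lexicographic order. Used to
#' define the genome-wide gene order for copy-number inference.
#'
#' @param chroms Character vector of chromosome names.
#' @return An integer rank vector, usable inside `order()`.
#' @examples
#' chroms <- c("chr10", "chr2", "chrX", "chr1")
#' chroms[order(chromosome_rank(chroms))]
#' @export
chromosome_rank <- function(chroms) {
  stripped <- sub("^chr", "", chroms, ignore.case = TRUE)
  canonical <- c(as.character(1:22), "X", "Y", "M", "MT")
  idx <- match(toupper(stripped), canonical)
  # unknown contigs rank after canonical ones, alphabetically
  extra <- sort(unique(chroms[is.na(idx)]))
  idx[is.na(idx)] <- length(canonical) + match(chroms[is.na(idx)], extra)
  idx
}

#' Row-wise moving average with truncated windows
#'
#' Centred moving average along the columns of a matrix, computed per row.
#' Windows are truncated at the matrix edges: the first column averages only
#' the `(w + 1)/2` values available to its right, and so on, so no padding
#' value is ever invented.
#'
#' @param m Numeric matrix (rows = cells, columns = ordered positions).
#' @param w Odd positive integer window width. `w = 1` returns `m` unchanged.
#' @return Matrix of the same dimension.
#' @keywords internal
row_moving_average <- function(m, w) {
  stopifnot(is.matrix(m), w >= 1, w %% 2 == 1)
  if (w == 1 || ncol(m) == 1) return(m)
  g <- ncol(m)
  half <- (w - 1) / 2
  # cumulative sums along columns; cs[, j+1] = sum of cols 1..j
  cs <- cbind(0, t(apply(m, 1, cumsum)))
  lo <- pmax(seq_len(g) - half, 1L)    # first column in each window
  hi <- pmin(seq_len(g) + half, g)     # last column in each window
  out <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(m))
  dimnames(out) <- dimnames(m)
  out
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 allow_inf = FALSE) {
  ok_value <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (is.finite(x) || (allow_inf && is.infinite(x) && x > 0))
  if (!ok_value || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
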