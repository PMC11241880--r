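#' Cumulative sum scaling (CSS) normalization
#'
#' Divides each sample's counts by the cumulative sum of its counts up to a
#' quantile of the positive counts, then rescales to a common constant. This
#' damps the influence of a few dominant taxa on between-sample comparisons
#' while preserving zeros and the within-sample rank order.
#'
#' For sample *j* the scaling factor is `s_j = sum(counts <= q_j)` where `q_j`
#' is the nearest-rank `quantile_l` quantile of the *positive* counts
#' (`ceil(l * n_pos)`-th smallest); normalized values are
#' `count / s_j * scale_to`.
#'
#' @param ct Count tibble.
#' @param quantile_l Quantile in (0, 1] used for the cumulative sum; default
#'   0.5 (the median of the positive counts).
#' @param scale_to Common scale constant; default 1000.
#' @return A normalized tibble with attributes `scaling_factors` (named per
#'   sample) and `method` (`"css"`).
#' @examples
#' ct <- tibble::tibble(taxon_id = c("a", "b"), S1 = c(2L, 2L), S2 = c(1L, 3L))
#' css_normalize(ct)
#' @export
css_normalize <- function(ct, quantile_l = 0.5, scale_to = 1000) {
  validate_count_table(ct)
  stopifnot(quantile_l > 0, quantile_l <= 1, scale_to > 0)
  m <- ct_matrix(ct)
  zero_samples <- colnames(m)[colSums(m) == 0]
  if (length(zero_samples)) {
    abort(sprintf("all-zero sample(s) cannot be CSS-normalized: %s",
                  paste(zero_samples, collapse = ", ")))
  }
  s <- vapply(seq_len(ncol(m)), function(j) {
    pos <- sort(m[m[, j] > 0, j])
    q <- pos[ceiling(quantile_l * length(pos))]
    sum(m[m[, j] <= q, j])
  }, numeric(1))
  names(s) <- colnames(m)
  norm <- sweep(m, 2, s, `/`) * scale_to
  out <- matrix_to_ct(norm)
  attr(out, "scaling_factors") <- s
  attr(out, "method") <- "css"
  out
}

#' Per-sample relative abundances
#'
#' Rescales every sample to sum to one. Zeros are preserved.
#'
#' @param ct Count or normalized tibble.
#' @return Tibble of the same shape with `method` attribute `"relative"`.
#' @export
relative_abundance <- function(ct) {
  validate_count_table(ct, integer_counts = FALSE)
  m <- ct_matrix(ct)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(sprintf("all-zero sample(s): %s", paste(colnames(m)[tot == 0], collapse = ", ")))
  }
  out <- matrix_to_ct(sweep(m, 2, tot, `/`))
  attr(out, "method") <- "relative"
  out
}
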