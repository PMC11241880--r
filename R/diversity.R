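#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))` with `f1` singletons and `f2`
#' doubletons, the bias-corrected form that stays defined when no doubletons
#' are observed. The estimate never falls below the observed richness.
#'
#' @param counts Non-negative integer vector of one sample's taxon counts.
#' @return The Chao1 estimate, or `NA_real_` for an empty/all-zero sample.
#' @examples
#' chao1(c(5, 1, 1, 2)) # 4.5
#' @export
chao1 <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0), all(counts == floor(counts)))
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(NA_real_)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Per-sample alpha-diversity profile
#'
#' Observed richness, Chao1 (counts only), Shannon entropy in nats, Simpson
#' diversity `1 - sum(p^2)` and Pielou's evenness `H / ln(S_obs)` (undefined
#' for single-taxon samples).
#'
#' @param ct Count tibble (integer counts; Chao1 requires them) or any
#'   non-negative abundance tibble with `with_chao1 = FALSE`.
#' @param with_chao1 Compute the Chao1 column (requires integer counts).
#' @return A tibble with one row per sample: `sample_id`, `observed`,
#'   `chao1`, `shannon`, `simpson`, `pielou`.
#' @examples
#' ct <- tibble::tibble(taxon_id = letters[1:4], S1 = c(1L, 1L, 1L, 1L))
#' alpha_diversity(ct)
#' @export
alpha_diversity <- function(ct, with_chao1 = TRUE) {
  validate_count_table(ct, integer_counts = with_chao1)
  m <- ct_matrix(ct)
  if (any(colSums(m) == 0)) {
    abort(sprintf("all-zero sample(s): %s",
                  paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  purrr::map_dfr(colnames(m), function(s) {
    x <- m[, s]
    pos <- x[x > 0]
    p <- pos / sum(pos)
    s_obs <- length(pos)
    h <- -sum(p * log(p))
    tibble(
      sample_id = s,
      observed = s_obs,
      chao1 = if (with_chao1) chao1(x) else NA_real_,
      shannon = h,
      simpson = 1 - sum(p^2),
      pielou = if (s_obs > 1) h / log(s_obs) else NA_real_
    )
  })
}

#' Boxplots of alpha-diversity metrics by a metadata factor
#'
#' @param div Output of [alpha_diversity()].
#' @param md Sample metadata tibble.
#' @param by Name of the metadata column to group by.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(div, md, by = "treatment") {
  dat <- div %>%
    left_join(md, by = "sample_id") %>%
    tidyr::pivot_longer(c("chao1", "shannon", "simpson", "pielou"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[by]], y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = by, y = NULL) +
    ggplot2::theme_minimal()
}
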