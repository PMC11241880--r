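#' Prioritize taxa across phenotype-taxon networks
#'
#' Ranks taxa by their mean composite centrality across a set of scored
#' phenotype-taxon networks. Taxa below the prevalence floor are removed
#' first (filter precedes ranking, so a perfectly central but rare taxon is
#' excluded). By default the mean is taken over the networks in which a taxon
#' appears, with the appearance count reported; a zero-filled mean over all
#' networks is reported alongside. Ties break by descending prevalence then
#' identifier.
#'
#' @param scores Named list of score tibbles (one per network, from
#'   [phona_node_scores()] or [composite_score()]).
#' @param prevalence Tibble `taxon_id`, `prevalence` over all samples.
#' @param min_prevalence Prevalence floor, default 0.2.
#' @param top_k Number of taxa to return, default 20 (all survivors when
#'   fewer, with a message).
#' @return A tibble `taxon_id`, `mean_composite`, `mean_composite_zero_filled`,
#'   `n_networks`, `prevalence`, `rank`.
#' @export
prioritize <- function(scores, prevalence, min_prevalence = 0.2, top_k = 20) {
  stopifnot(is.list(scores), length(scores) >= 1)
  if (is.null(names(scores)) || any(names(scores) == "")) {
    names(scores) <- sprintf("network_%02d", seq_along(scores))
  }
  long <- purrr::imap_dfr(scores, function(s, nm) {
    s %>% select("taxon_id", "composite") %>% mutate(network = nm)
  })
  n_net <- length(scores)
  ranked <- long %>%
    group_by(.data$taxon_id) %>%
    summarise(mean_composite = mean(.data$composite),
              mean_composite_zero_filled = sum(.data$composite) / n_net,
              n_networks = dplyr::n(), .groups = "drop") %>%
    left_join(prevalence, by = "taxon_id") %>%
    mutate(prevalence = dplyr::coalesce(.data$prevalence, 0)) %>%
    filter(.data$prevalence >= min_prevalence) %>%
    arrange(desc(.data$mean_composite), desc(.data$prevalence), .data$taxon_id) %>%
    mutate(rank = row_number())
  if (nrow(ranked) < top_k) {
    inform(sprintf("only %d taxa survive the prevalence filter (top_k = %d)",
                   nrow(ranked), top_k))
  }
  out <- ranked %>% slice_head(n = top_k)
  class(out) <- c("rhizo_prioritization", class(out))
  out
}

#' Plot a prioritization report
#'
#' Lollipop chart of mean composite centrality for the ranked taxa.
#'
#' @param object A tibble from [prioritize()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhizo_prioritization
#' @export
autoplot.rhizo_prioritization <- function(object, ...) {
  dat <- object %>% mutate(taxon_id = stats::reorder(.data$taxon_id, .data$mean_composite))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mean_composite, y = .data$taxon_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$mean_composite,
                                       yend = .data$taxon_id), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$prevalence)) +
    ggplot2::labs(x = "mean composite centrality", y = NULL, size = "prevalence") +
    ggplot2::theme_minimal()
}
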