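#' Reference topology summaries for condition-specific networks
#'
#' Ten-metric topology summaries for the 16 condition-specific co-occurrence
#' networks (treatment x cultivar x growth stage) of the soybean rhizosphere
#' field study this package emulates, one table per association method. Rows
#' are named `<stage>-<treatment>-<cultivar>`; columns match
#' [summarize_topology()]. These values are used by the test suite and the
#' acceptance script to check topology identities (connectance and mean
#' degree against node and edge counts) and table-level summaries, and
#' several degenerate rows force unique graph structures (e.g. the
#' 6-node/6-edge/2-component row is necessarily two disjoint triangles).
#'
#' @param method `"spearman"` or `"pearson"`.
#' @return A 16-row tibble.
#' @examples
#' mean(reference_topology("spearman")$edge_count)
#' @export
reference_topology <- function(method = c("spearman", "pearson")) {
  method <- match.arg(method)
  path <- system.file("extdata", sprintf("reference_topology_%s.tsv", method),
                      package = "rhizonet", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    network = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}
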