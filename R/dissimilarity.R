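#' Between-sample dissimilarity matrix
#'
#' Bray-Curtis and Euclidean distances on abundances, Jaccard on
#' presence/absence (`1 - |intersection| / |union|` of detected taxa). Pairs
#' of all-zero samples are undefined under Bray-Curtis/Jaccard and are set to
#' 0 with a warning.
#'
#' @param nt Normalized (or raw) abundance tibble.
#' @param metric One of `"bray_curtis"`, `"euclidean"`, `"jaccard"`.
#' @return A `dist` object over the samples, with attribute `metric`.
#' @examples
#' ct <- tibble::tibble(taxon_id = c("a", "b"), S1 = c(1, 2), S2 = c(3, 0))
#' dissimilarity(ct, "bray_curtis")
#' @export
dissimilarity <- function(nt, metric = c("bray_curtis", "euclidean", "jaccard")) {
  metric <- match.arg(metric)
  validate_count_table(nt, integer_counts = FALSE)
  m <- t(ct_matrix(nt)) # samples x taxa for vegdist
  if (nrow(m) < 2) abort("dissimilarity needs at least two samples")
  d <- suppressWarnings(switch(metric,
    bray_curtis = vegan::vegdist(m, method = "bray"),
    euclidean = stats::dist(m, method = "euclidean"),
    jaccard = vegan::vegdist(m > 0, method = "jaccard", binary = TRUE)
  )) # vegdist warns about all-zero samples; handled explicitly below
  if (any(is.na(d))) {
    warn(sprintf("%d undefined distance(s) between all-zero samples set to 0", sum(is.na(d))))
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}
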