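#' Per-taxon prevalence
#'
#' Fraction of samples in which a taxon has a nonzero count. Presence is
#' judged on the supplied values directly, so prevalence is invariant to any
#' per-sample rescaling that preserves zeros (CSS, relative abundance).
#'
#' @param ct Count or abundance tibble.
#' @return A tibble `taxon_id`, `prevalence`.
#' @export
prevalence <- function(ct) {
  validate_count_table(ct, integer_counts = FALSE)
  m <- ct_matrix(ct)
  if (ncol(m) < 1) abort("prevalence needs at least one sample")
  tibble(taxon_id = rownames(m), prevalence = unname(rowMeans(m > 0)))
}

#' Core taxa by prevalence threshold
#'
#' Taxa detected in at least `threshold` of all samples, the standard
#' core-microbiome definition. Evaluated on relative abundances by convention
#' (presence/absence is unchanged by the transform).
#'
#' @param nt Relative-abundance (or any) abundance tibble.
#' @param threshold Prevalence threshold in `[0, 1]`; default 0.5.
#' @return A tibble `taxon_id`, `prevalence` sorted by descending prevalence
#'   then identifier.
#' @export
core_taxa <- function(nt, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  prevalence(nt) %>%
    filter(if (threshold > 0) .data$prevalence >= threshold else .data$prevalence > 0) %>%
    arrange(desc(.data$prevalence), .data$taxon_id)
}

#' Taxa unique to one level of an experimental factor
#'
#' A taxon is unique to level L when it is detected in at least one sample at
#' L and in no sample at any other level of the factor. For a treatment-style
#' factor whose levels only become meaningful after an intervention, supply
#' `baseline_stage`: samples at that growth stage are removed before
#' uniqueness is assessed, and taxa that were already present at baseline are
#' excluded from every uniqueness list.
#'
#' @param ct Count tibble.
#' @param md Sample metadata with a `sample_id` column and the factor column.
#' @param factor_name Metadata column to assess.
#' @param baseline_stage Optional growth-stage level to treat as baseline
#'   (requires a `growth_stage` column in `md`).
#' @return A tibble `level`, `taxon_id` listing unique taxa per level;
#'   pairwise disjoint across levels by construction.
#' @export
unique_taxa <- function(ct, md, factor_name, baseline_stage = NULL) {
  validate_count_table(ct, integer_counts = FALSE)
  if (!factor_name %in% names(md)) abort(sprintf("metadata has no column '%s'", factor_name))
  m <- ct_matrix(ct)
  md <- md[match(colnames(m), md$sample_id), ]
  if (anyNA(md$sample_id)) abort("metadata missing rows for some samples")
  baseline_taxa <- character(0)
  if (!is.null(baseline_stage)) {
    if (!"growth_stage" %in% names(md)) abort("baseline_stage requires a growth_stage column")
    base <- md$growth_stage == baseline_stage
    baseline_taxa <- rownames(m)[rowSums(m[, base, drop = FALSE] > 0) > 0]
    m <- m[, !base, drop = FALSE]
    md <- md[!base, ]
  }
  lv <- unique(as.character(md[[factor_name]]))
  if (length(lv) < 2) abort(sprintf("factor '%s' has fewer than two levels", factor_name))
  present <- vapply(lv, function(l) {
    rowSums(m[, md[[factor_name]] == l, drop = FALSE] > 0) > 0
  }, logical(nrow(m)))
  n_levels <- rowSums(present)
  purrr::map_dfr(lv, function(l) {
    uniq <- rownames(m)[present[, l] & n_levels == 1]
    uniq <- setdiff(uniq, baseline_taxa)
    tibble(level = l, taxon_id = sort(uniq))
  })
}
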