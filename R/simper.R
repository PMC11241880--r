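#' Similarity percentage (SIMPER) decomposition
#'
#' Decomposes the mean between-group Bray-Curtis dissimilarity into per-taxon
#' contributions. For each between-group sample pair (j, k) the taxon-i share
#' is `|x_ij - x_ik| / sum_t(x_tj + x_tk)`; contributions are the means of
#' these shares over all between-group pairs, so they sum exactly to the mean
#' between-group Bray-Curtis dissimilarity. A permutation p-value per taxon is
#' the fraction of group-label permutations with a contribution at least as
#' large as observed.
#'
#' @param nt Abundance tibble (normalized or raw).
#' @param grouping Two-level factor over samples (in column order).
#' @param n_perm Number of label permutations (default 199).
#' @param seed Integer seed.
#' @return A tibble with one row per taxon: `taxon_id`, `contribution`
#'   (absolute), `percent`, `p.value`, sorted by descending contribution.
#' @examples
#' nt <- tibble::tibble(taxon_id = c("a", "b"), S1 = c(1, 2), S2 = c(3, 0))
#' simper(nt, c("g1", "g2"), n_perm = 19)
#' @export
simper <- function(nt, grouping, n_perm = 199, seed = 1L) {
  validate_count_table(nt, integer_counts = FALSE)
  m <- ct_matrix(nt)
  grouping <- factor(grouping)
  if (nlevels(droplevels(grouping)) != 2) abort("simper requires exactly two groups")
  if (length(grouping) != ncol(m)) abort("grouping length must match sample count")
  obs <- simper_contrib(m, grouping)
  perm_ge <- with_seed(seed, {
    ge <- rep(0, nrow(m))
    for (k in seq_len(n_perm)) {
      contrib_k <- simper_contrib(m, grouping[sample.int(ncol(m))])
      ge <- ge + (contrib_k >= obs)
    }
    ge
  })
  p <- (1 + perm_ge) / (1 + n_perm)
  total <- sum(obs)
  tibble(
    taxon_id = rownames(m),
    contribution = obs,
    percent = if (total > 0) 100 * obs / total else rep(0, length(obs)),
    p.value = p
  ) %>% arrange(desc(.data$contribution), .data$taxon_id)
}

# Mean per-taxon contribution over between-group sample pairs.
simper_contrib <- function(m, grouping) {
  lv <- levels(droplevels(grouping))
  ja <- which(grouping == lv[1])
  jb <- which(grouping == lv[2])
  contrib <- rep(0, nrow(m))
  for (j in ja) {
    for (k in jb) {
      denom <- sum(m[, j] + m[, k])
      if (denom > 0) contrib <- contrib + abs(m[, j] - m[, k]) / denom
    }
  }
  unname(contrib / (length(ja) * length(jb)))
}
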