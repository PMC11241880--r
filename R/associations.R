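#' Pairwise taxon-taxon association statistics
#'
#' Computes a correlation coefficient for every unordered taxon pair:
#' Spearman's rho (average-rank transform followed by the product-moment
#' correlation) or Pearson's r. Two-sided p-values use the t approximation
#' with n - 2 degrees of freedom; q-values are Benjamini-Hochberg adjusted
#' over all pairs tested in the run. Taxa with zero variance cannot be
#' correlated; their pairs are excluded from testing (with a message).
#'
#' @param nt Abundance tibble (CSS-normalized counts in typical use).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble with columns `taxon_i`, `taxon_j` (i < j), `coefficient`,
#'   `p`, `q`, `sign`, and attribute `method`.
#' @examples
#' nt <- tibble::tibble(taxon_id = c("a", "b", "c"),
#'                      S1 = c(1, 3, 2), S2 = c(2, 1, 4), S3 = c(3, 2, 6),
#'                      S4 = c(4, 4, 8))
#' pairwise_associations(nt)
#' @export
pairwise_associations <- function(nt, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  validate_count_table(nt, integer_counts = FALSE)
  m <- ct_matrix(nt)
  n <- ncol(m)
  if (n < 4) abort("pairwise_associations needs at least 4 samples")
  if (nrow(m) < 2) abort("pairwise_associations needs at least 2 taxa")
  constant <- apply(m, 1, function(x) stats::var(x) == 0)
  if (any(constant)) {
    inform(sprintf("excluding %d zero-variance taxon(a) from association testing: %s",
                   sum(constant), paste(rownames(m)[constant], collapse = ", ")))
    m <- m[!constant, , drop = FALSE]
  }
  if (nrow(m) < 2) {
    out <- tibble(taxon_i = character(), taxon_j = character(),
                  coefficient = numeric(), p = numeric(), q = numeric(),
                  sign = integer())
    attr(out, "method") <- method
    return(out)
  }
  x <- if (method == "spearman") t(apply(m, 1, rank)) else m
  cc <- stats::cor(t(x))
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  r <- cc[idx]
  r <- pmin(1, pmax(-1, r))
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- ifelse(abs(r) >= 1, 0, 2 * pt(tt, df = n - 2, lower.tail = FALSE))
  out <- tibble(
    taxon_i = rownames(m)[idx[, 1]],
    taxon_j = rownames(m)[idx[, 2]],
    coefficient = r,
    p = p,
    q = bh_fdr(p),
    sign = as.integer(base::sign(r))
  ) %>% arrange(.data$taxon_i, .data$taxon_j)
  attr(out, "method") <- method
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; the mapping back to
#' input positions is order preserving. A thin, named wrapper over
#' [stats::p.adjust()] so the gating rule used throughout the pipeline is
#' explicit.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.03, 0.04))
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Associations between prioritized taxa and phenotypes
#'
#' Spearman associations (with BH q-values) among a set of taxa and between
#' each taxon and each phenotype, as used to characterize prioritized network
#' members. Constant phenotypes are excluded with a message.
#'
#' @param nt Abundance tibble restricted (or restrictable via `taxa`) to the
#'   taxa of interest.
#' @param ph Long phenotype tibble (`sample_id`, `phenotype`, `value`).
#' @param taxa Optional character vector of taxon ids to keep.
#' @return A list with tibbles `taxon_taxon` and `taxon_phenotype`, both with
#'   `coefficient`, `p`, `q`, `sign` columns.
#' @export
node_phenotype_associations <- function(nt, ph, taxa = NULL) {
  validate_count_table(nt, integer_counts = FALSE)
  validate_phenotype_table(ph)
  if (!is.null(taxa)) nt <- nt %>% filter(.data$taxon_id %in% taxa)
  samples <- intersect(ct_samples(nt), unique(ph$sample_id))
  if (length(samples) < 4) abort("need at least 4 shared samples")
  nt <- nt[c("taxon_id", sort(samples))]
  tt <- pairwise_associations(nt, method = "spearman")
  m <- ct_matrix(nt)
  wide <- ph %>%
    filter(.data$sample_id %in% samples) %>%
    tidyr::pivot_wider(names_from = "phenotype", values_from = "value") %>%
    arrange(.data$sample_id)
  pv <- as.matrix(wide[setdiff(names(wide), "sample_id")])
  keep <- apply(pv, 2, function(x) stats::var(x) > 0)
  if (any(!keep)) {
    inform(sprintf("excluding constant phenotype(s): %s",
                   paste(colnames(pv)[!keep], collapse = ", ")))
    pv <- pv[, keep, drop = FALSE]
  }
  n <- length(samples)
  tp <- purrr::map_dfr(rownames(m), function(tx) {
    xr <- rank(m[tx, sort(samples)])
    purrr::map_dfr(colnames(pv), function(pn) {
      r <- stats::cor(xr, rank(pv[, pn]))
      tstat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      tibble(taxon_id = tx, phenotype = pn, coefficient = r,
             p = if (abs(r) >= 1) 0 else 2 * pt(tstat, df = n - 2, lower.tail = FALSE))
    })
  })
  tp$q <- bh_fdr(tp$p)
  tp$sign <- as.integer(sign(tp$coefficient))
  list(taxon_taxon = tt, taxon_phenotype = tp)
}
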