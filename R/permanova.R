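#' Permutational multivariate analysis of variance (one factor, optional strata)
#'
#' Distance-based pseudo-F test of a single grouping factor. Sums of squares
#' follow the classic decomposition on squared distances:
#' `SS_total = sum(d_ij^2) / n` over all pairs, `SS_within` the analogous
#' within-group sum with each group's pair sum divided by its size, and
#' `pseudo_F = (SS_between / (a - 1)) / (SS_within / (n - a))`. The p-value
#' is `(1 + #{permuted F >= observed F}) / (1 + n_perm)`; when a stratum
#' factor is given, labels are shuffled only within strata, mirroring designs
#' where samples are exchangeable only within a field block.
#'
#' @param dm A `dist` object (e.g. from [dissimilarity()]).
#' @param grouping Factor (or coercible) of group labels, one per sample, in
#'   the order of the distance matrix.
#' @param strata Optional factor restricting permutations to within-stratum
#'   shuffles.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @return A `rhizo_permanova` object; see [tidy()] / [glance()] for tabular
#'   views. Fields: `pseudo_F`, `R2`, `p`, `df`, `n_perm`.
#' @examples
#' d <- dist(c(0, 1, 10, 11))
#' fit <- permanova(d, c("A", "A", "B", "B"), n_perm = 199, seed = 1)
#' glance(fit)
#' @export
permanova <- function(dm, grouping, strata = NULL, n_perm = 9999, seed = 1L) {
  stopifnot(inherits(dm, "dist"))
  n <- attr(dm, "Size")
  grouping <- factor(grouping)
  if (length(grouping) != n) abort("grouping length must match the distance matrix")
  if (nlevels(droplevels(grouping)) < 2) abort("grouping must have at least two levels")
  if (!is.null(strata)) {
    strata <- factor(strata)
    if (length(strata) != n) abort("strata length must match the distance matrix")
  }
  d2 <- as.matrix(dm)^2
  a <- nlevels(droplevels(grouping))
  obs <- permanova_f(d2, grouping, a)
  perm_f <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- permute_within(n, strata)
      permanova_f(d2, grouping[idx], a)$f
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= obs$f)) / (1 + n_perm)
  structure(list(
    pseudo_F = obs$f, R2 = obs$r2, p = p,
    df = c(between = a - 1L, within = n - a),
    n_perm = as.integer(n_perm),
    strata = !is.null(strata),
    metric = attr(dm, "metric") %||% NA_character_
  ), class = "rhizo_permanova")
}

permanova_f <- function(d2, grouping, a) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in levels(grouping)) {
    idx <- which(grouping == lv)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- if (ss_within <= 0) Inf else (ss_between / (a - 1)) / (ss_within / (n - a))
  list(f = f, r2 = if (ss_total > 0) ss_between / ss_total else NA_real_)
}

permute_within <- function(n, strata) {
  if (is.null(strata)) return(sample.int(n))
  idx <- seq_len(n)
  for (lv in levels(strata)) {
    pos <- which(strata == lv)
    if (length(pos) > 1) idx[pos] <- pos[sample.int(length(pos))]
  }
  idx
}

#' @export
print.rhizo_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations%s)\n",
              x$metric, x$pseudo_F, x$R2, x$p, x$n_perm,
              if (x$strata) ", stratified" else ""))
  invisible(x)
}

#' @rdname permanova
#' @param x A `rhizo_permanova` object.
#' @param ... Unused.
#' @method tidy rhizo_permanova
#' @export
tidy.rhizo_permanova <- function(x, ...) {
  tibble(term = "grouping", df = x$df[["between"]], pseudo_F = x$pseudo_F,
         R2 = x$R2, p.value = x$p)
}

#' @rdname permanova
#' @method glance rhizo_permanova
#' @export
glance.rhizo_permanova <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p.value = x$p,
         n_perm = x$n_perm, stratified = x$strata)
}
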