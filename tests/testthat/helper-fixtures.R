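# Shared fixtures and independent oracles used across the suite.

# Small random count table (taxa x samples) as a tibble.
random_count_table <- function(n_taxa = 6, n_samples = 5, seed = 1,
                               lambda = 8, zero_prob = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_taxa * n_samples, lambda) *
                  rbinom(n_taxa * n_samples, 1, 1 - zero_prob),
                nrow = n_taxa,
                dimnames = list(sprintf("tx%02d", seq_len(n_taxa)),
                                sprintf("S%02d", seq_len(n_samples))))
    # keep every sample non-empty
    for (j in which(colSums(m) == 0)) m[1, j] <- 1L
    out <- tibble::as_tibble(m)
    out <- dplyr::bind_cols(tibble::tibble(taxon_id = rownames(m)), out)
    out[-1] <- lapply(out[-1], as.integer)
    out
  })
}

# Network from a plain edge list (character vectors from/to).
edge_network <- function(from, to, coefficient = 1, sign = 1L) {
  assocs <- tibble::tibble(taxon_i = from, taxon_j = to,
                           coefficient = coefficient, p = 0, q = 0,
                           sign = as.integer(sign))
  build_network(assocs, rho_threshold = 0, q_threshold = 1)
}

# Round half away from zero to two decimals, as printed summary tables do
# (base round() uses banker's rounding: round(0.225, 2) == 0.22).
round2 <- function(x) floor(x * 100 + 0.5) / 100

# --- independent oracles ----------------------------------------------------

# All set partitions of a vector (Bell-number enumeration, recursive).
set_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(x[1], q[[k]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

# Modularity by direct formula from an edge data frame and a membership list.
modularity_oracle <- function(edges, partition_list) {
  m <- nrow(edges)
  nodes <- unique(c(edges$taxon_i, edges$taxon_j))
  deg <- table(factor(c(edges$taxon_i, edges$taxon_j), levels = nodes))
  q <- 0
  for (grp in partition_list) {
    m_c <- sum(edges$taxon_i %in% grp & edges$taxon_j %in% grp)
    d_c <- sum(deg[grp])
    q <- q + m_c / m - (d_c / (2 * m))^2
  }
  q
}

# Maximum modularity over all partitions of a small graph.
max_modularity_oracle <- function(net) {
  nodes <- net$nodes$taxon_id
  best <- -Inf
  for (p in set_partitions(nodes)) {
    q <- modularity_oracle(net$edges, p)
    if (q > best) best <- q
  }
  best
}

# PERMANOVA pseudo-F by direct formula (independent of package internals).
permanova_f_oracle <- function(d, grouping) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  grouping <- factor(grouping)
  a <- nlevels(grouping)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (lv in levels(grouping)) {
    idx <- which(grouping == lv)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Exact permutation p by complete enumeration of label orderings (n <= 8).
permanova_p_enumeration <- function(d, grouping) {
  n <- attr(d, "Size")
  perms <- gtools_permutations(n)
  f_obs <- permanova_f_oracle(d, grouping)
  f_all <- apply(perms, 1, function(idx) permanova_f_oracle(d, grouping[idx]))
  mean(f_all >= f_obs - 1e-12)
}

# All permutations of 1..n without external packages.
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# Discrete power-law sampler by inverse-CDF (zeta normalization).
rzeta <- function(n, alpha, xmin = 1, xmax = 1e5) {
  support <- xmin:xmax
  pmf <- support^(-alpha)
  pmf <- pmf / sum(pmf)
  sample(support, n, replace = TRUE, prob = pmf)
}
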