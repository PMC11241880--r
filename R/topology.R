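#' Freeman degree centralization
#'
#' `sum(d_max - d_i) / ((N - 1) * (N - 2))`: 0 for any regular graph, 1 for a
#' star. Graphs with fewer than three nodes return 0 by convention (with a
#' message), since the normalizer vanishes.
#'
#' @param net A `rhizo_network`.
#' @return A number in `[0, 1]`.
#' @export
centralization_degree <- function(net) {
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 3) {
    inform("centralization is undefined for fewer than 3 nodes; returning 0")
    return(0)
  }
  d <- igraph::degree(g)
  sum(max(d) - d) / ((n - 1) * (n - 2))
}

#' Walktrap community detection
#'
#' Agglomerative merging driven by short random-walk distances, applied
#' independently within each connected component so that distinct components
#' never share a community; within a component the merge-tree cut maximizing
#' Newman-Girvan modularity is taken. Edge signs and weights are ignored
#' (community structure is computed on the topology alone).
#'
#' @param net A `rhizo_network`.
#' @param walk_steps Random-walk length, default 4.
#' @return A tibble `taxon_id`, `community` (integer labels).
#' @export
walktrap_communities <- function(net, walk_steps = 4) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) return(tibble(taxon_id = character(), community = integer()))
  comp <- igraph::components(g)
  out <- integer(igraph::vcount(g))
  offset <- 0L
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vids)
    if (igraph::vcount(sub) == 1 || igraph::ecount(sub) == 0) {
      memb <- rep(1L, igraph::vcount(sub))
    } else {
      wt <- igraph::cluster_walktrap(sub, steps = walk_steps, weights = NULL)
      memb <- as.integer(igraph::membership(wt))
    }
    out[vids] <- memb + offset
    offset <- offset + max(memb)
  }
  tibble(taxon_id = igraph::V(g)$name, community = out)
}

#' Newman-Girvan modularity of a node partition
#'
#' `Q = sum_c [ m_c / m - (D_c / (2 m))^2 ]` with `m` the edge count, `m_c`
#' the intra-community edge count and `D_c` the total degree of community c.
#' Edgeless graphs have undefined modularity (`NA`).
#'
#' @param net A `rhizo_network`.
#' @param partition Tibble `taxon_id`, `community` covering all nodes (e.g.
#'   from [walktrap_communities()]).
#' @return Modularity Q in `[-0.5, 1]`, or `NA_real_` when there are no edges.
#' @export
modularity_q <- function(net, partition) {
  stopifnot(inherits(net, "rhizo_network"))
  if (!setequal(partition$taxon_id, net$nodes$taxon_id)) {
    abort("partition must cover exactly the network's nodes")
  }
  m <- nrow(net$edges)
  if (m == 0) return(NA_real_)
  memb <- setNames(partition$community, partition$taxon_id)
  deg <- table(factor(c(net$edges$taxon_i, net$edges$taxon_j),
                      levels = net$nodes$taxon_id))
  q <- 0
  for (comm in unique(memb)) {
    in_c <- names(memb)[memb == comm]
    m_c <- sum(net$edges$taxon_i %in% in_c & net$edges$taxon_j %in% in_c)
    d_c <- sum(deg[in_c])
    q <- q + m_c / m - (d_c / (2 * m))^2
  }
  q
}

#' Kleinberg hub scores by power iteration
#'
#' The HITS hub vector of an undirected graph: the principal eigenvector of
#' the adjacency matrix, computed by power iteration on the Perron-shifted
#' matrix `I + A` from the uniform vector with sup-norm scaling, so the
#' maximum score is 1. The shift guarantees convergence on bipartite
#' components and resolves the sign degeneracy of `A^2` in the direction HITS
#' uses (a star scores its center 1 and its leaves `1/sqrt(k)`). The uniform
#' start gives the symmetric limit on graphs whose components are
#' interchangeable: all six nodes of two disjoint triangles score 1. Edge
#' signs are ignored.
#'
#' @param net A `rhizo_network` with at least one edge (empty networks return
#'   an empty tibble).
#' @param tol Sup-norm convergence tolerance, default 1e-10.
#' @param max_iter Iteration cap, default 1e6.
#' @return A tibble `taxon_id`, `hub` with scores in `[0, 1]`.
#' @export
hub_scores <- function(net, tol = 1e-10, max_iter = 1e6) {
  stopifnot(inherits(net, "rhizo_network"))
  if (nrow(net$edges) == 0) return(tibble(taxon_id = character(), hub = numeric()))
  ids <- net$nodes$taxon_id
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  a[cbind(net$edges$taxon_i, net$edges$taxon_j)] <- 1
  a[cbind(net$edges$taxon_j, net$edges$taxon_i)] <- 1
  a2 <- a + diag(n)
  v <- rep(1, n)
  for (it in seq_len(max_iter)) {
    w <- as.numeric(a2 %*% v)
    w <- w / max(w)
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  tibble(taxon_id = ids, hub = v)
}

#' Count network hubs
#'
#' Nodes whose hub score strictly exceeds the threshold.
#'
#' @param scores Tibble from [hub_scores()] (or a numeric vector).
#' @param threshold Hub threshold, default 0.2.
#' @return Integer count.
#' @export
hub_count <- function(scores, threshold = 0.2) {
  s <- if (is.data.frame(scores)) scores$hub else scores
  sum(s > threshold)
}

#' Discrete power-law fit to a degree distribution
#'
#' Maximum-likelihood fit of `P(X = x) ~ x^(-alpha)` on `x >= xmin` for
#' integer degrees: for every candidate `xmin` the exponent maximizes the
#' zeta likelihood on the tail, and the retained `xmin` minimizes the
#' Kolmogorov-Smirnov distance between the empirical and fitted CDFs. The fit
#' is undefined (and reported as such, rather than NaN) when fewer than two
#' distinct degree values are available, as for regular graphs.
#'
#' @param degrees Vector of positive integer degrees.
#' @return A list with `alpha`, `xmin`, `ks_stat`, `defined`.
#' @export
power_law_fit <- function(degrees) {
  x <- degrees[degrees > 0]
  stopifnot(length(x) >= 1, all(x == floor(x)))
  if (length(unique(x)) < 2) {
    return(list(alpha = NA_real_, xmin = NA_integer_, ks_stat = NA_real_,
                defined = FALSE))
  }
  cands <- sort(unique(x))
  cands <- cands[vapply(cands, function(xm) length(unique(x[x >= xm])) >= 2, logical(1))]
  best <- NULL
  for (xm in cands) {
    tail_x <- x[x >= xm]
    nll <- function(a) {
      v <- length(tail_x) * log(gen_zeta(a, xm)) + a * sum(log(tail_x))
      if (!is.finite(v)) 1e300 else v
    }
    alpha <- stats::optimize(nll, interval = c(1.01, 25))$minimum
    ks <- plfit_ks(tail_x, alpha, xm)
    if (is.null(best) || ks < best$ks_stat) {
      best <- list(alpha = alpha, xmin = as.integer(xm), ks_stat = ks, defined = TRUE)
    }
  }
  best
}

# Generalized (Hurwitz) zeta for integer shift: sum_{k >= xmin} k^-a.
# Direct tail summation with an Euler-Maclaurin remainder avoids the
# catastrophic cancellation of zeta(a) - partial_sum for large xmin or a.
gen_zeta <- function(a, xmin) {
  if (xmin == 1) return(pracma::zeta(a))
  k <- seq(xmin, xmin + 9999)
  sum(k^(-a)) + (xmin + 9999.5)^(1 - a) / (a - 1)
}

# KS distance between the empirical CDF of the tail and the fitted zeta CDF.
plfit_ks <- function(tail_x, alpha, xmin) {
  zx <- gen_zeta(alpha, xmin)
  support <- seq(xmin, max(tail_x))
  pmf <- support^(-alpha) / zx
  cdf_fit <- cumsum(pmf)
  cdf_emp <- vapply(support, function(v) mean(tail_x <= v), numeric(1))
  max(abs(cdf_emp - cdf_fit))
}

#' Friedman rank sum test across matched conditions
#'
#' Compares the ranking of two or more methods (columns) over matched
#' conditions (rows), with average ranks for ties; the statistic is referred
#' to a chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param metric_matrix Numeric matrix: conditions (blocks) in rows, methods
#'   (treatments) in columns; no missing cells.
#' @return A tibble `statistic`, `df`, `p.value`.
#' @examples
#' friedman_rank_test(cbind(a = c(2, 4, 6), b = c(1, 3, 5)))
#' @export
friedman_rank_test <- function(metric_matrix) {
  m <- as.matrix(metric_matrix)
  if (any(is.na(m))) abort("friedman_rank_test does not accept missing cells")
  if (nrow(m) < 2 || ncol(m) < 2) abort("need >= 2 conditions and >= 2 methods")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1))) {
    # every condition fully tied: no ranking information, statistic 0
    return(tibble(statistic = 0, df = ncol(m) - 1L, p.value = 1))
  }
  ft <- friedman.test(m)
  tibble(statistic = unname(ft$statistic), df = unname(ft$parameter),
         p.value = ft$p.value)
}

#' Ten-metric topology summary of a network
#'
#' The per-network summary used to compare condition-specific networks:
#' Freeman degree centralization, connected-component (cluster) count,
#' connectance `2E / (N (N - 1))`, edge count, giant component size, hub
#' count (Kleinberg hub score above `hub_threshold`), the Kolmogorov-Smirnov
#' statistic of the discrete power-law degree fit (undefined for regular
#' degree sequences), mean degree `2E / N`, Walktrap/Newman-Girvan
#' modularity, and node count.
#'
#' @param net A `rhizo_network`.
#' @param hub_threshold Hub score cutoff, default 0.2.
#' @param walk_steps Walktrap random-walk length, default 4.
#' @return A one-row tibble with columns `centralization_degree`,
#'   `cluster_count`, `connectance`, `edge_count`, `giant_component_size`,
#'   `hub_count`, `ks_stat`, `mean_degree`, `modularity`, `node_count`.
#' @examples
#' summarize_topology(fixture_graph("two_triangles"))
#' @export
summarize_topology <- function(net, hub_threshold = 0.2, walk_steps = 4) {
  stopifnot(inherits(net, "rhizo_network"))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    return(tibble(centralization_degree = NA_real_, cluster_count = 0L,
                  connectance = NA_real_, edge_count = 0L,
                  giant_component_size = 0L, hub_count = 0L,
                  ks_stat = NA_real_, mean_degree = NA_real_,
                  modularity = NA_real_, node_count = 0L))
  }
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  part <- walktrap_communities(net, walk_steps = walk_steps)
  pl <- if (e > 0) power_law_fit(deg[deg > 0]) else list(ks_stat = NA_real_)
  tibble(
    centralization_degree = if (n < 3) 0 else sum(max(deg) - deg) / ((n - 1) * (n - 2)),
    cluster_count = comp$no,
    connectance = if (n >= 2) 2 * e / (n * (n - 1)) else NA_real_,
    edge_count = as.integer(e),
    giant_component_size = as.integer(max(comp$csize)),
    hub_count = if (e > 0) hub_count(hub_scores(net), hub_threshold) else 0L,
    ks_stat = pl$ks_stat,
    mean_degree = 2 * e / n,
    modularity = modularity_q(net, part),
    node_count = as.integer(n)
  )
}
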