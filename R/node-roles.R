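#' Within-module degree z-score
#'
#' Standardizes each node's within-module degree against its module's mean
#' and *population* standard deviation (Guimera-Amaral convention):
#' `z_i = (k_i - mean(k_module)) / sd_pop(k_module)`, with `z = 0` whenever
#' the module standard deviation is zero (including singleton modules), so
#' degenerate modules never produce undefined scores.
#'
#' @param net A `rhizo_network`.
#' @param partition Tibble `taxon_id`, `community` covering the nodes.
#' @return A tibble `taxon_id`, `within_module_z`.
#' @export
within_module_z <- function(net, partition) {
  stopifnot(inherits(net, "rhizo_network"))
  if (!setequal(partition$taxon_id, net$nodes$taxon_id)) {
    abort("partition must cover exactly the network's nodes")
  }
  memb <- setNames(partition$community, partition$taxon_id)
  same <- memb[net$edges$taxon_i] == memb[net$edges$taxon_j]
  within_edges <- net$edges[same, ]
  k <- table(factor(c(within_edges$taxon_i, within_edges$taxon_j),
                    levels = net$nodes$taxon_id))
  k <- setNames(as.numeric(k), names(k))
  z <- vapply(net$nodes$taxon_id, function(v) {
    mod_nodes <- names(memb)[memb == memb[v]]
    km <- k[mod_nodes]
    s <- sqrt(mean((km - mean(km))^2))
    if (s == 0) 0 else (k[v] - mean(km)) / s
  }, numeric(1))
  tibble(taxon_id = net$nodes$taxon_id, within_module_z = unname(z))
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (k_is / k_i)^2` over modules s: 0 when all of a node's
#' links stay in one module (or the node has no links), approaching
#' `1 - 1/m` when links spread evenly over m modules.
#'
#' @inheritParams within_module_z
#' @return A tibble `taxon_id`, `participation`.
#' @export
participation_coefficient <- function(net, partition) {
  stopifnot(inherits(net, "rhizo_network"))
  if (!setequal(partition$taxon_id, net$nodes$taxon_id)) {
    abort("partition must cover exactly the network's nodes")
  }
  memb <- setNames(partition$community, partition$taxon_id)
  p <- vapply(net$nodes$taxon_id, function(v) {
    nbr <- c(net$edges$taxon_j[net$edges$taxon_i == v],
             net$edges$taxon_i[net$edges$taxon_j == v])
    if (length(nbr) == 0) return(0)
    shares <- table(memb[nbr]) / length(nbr)
    1 - sum(shares^2)
  }, numeric(1))
  tibble(taxon_id = net$nodes$taxon_id, participation = unname(p))
}

#' Composite centrality score
#'
#' Min-max normalizes the within-module z-score, participation coefficient
#' and hub score across a network's nodes and averages them with equal
#' weights. A metric that is constant across the network is uninformative and
#' maps every node to 0.5 rather than to an extreme.
#'
#' @param z Tibble from [within_module_z()].
#' @param p Tibble from [participation_coefficient()].
#' @param hub Tibble from [hub_scores()].
#' @return A tibble `taxon_id`, raw and normalized metrics, and `composite`
#'   (the mean of the three normalized values, in `[0, 1]`).
#' @export
composite_score <- function(z, p, hub) {
  ids <- z$taxon_id
  stopifnot(setequal(ids, p$taxon_id), setequal(ids, hub$taxon_id))
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0.5, length(x)) else (x - rng[1]) / diff(rng)
  }
  out <- tibble(taxon_id = ids) %>%
    left_join(z, by = "taxon_id") %>%
    left_join(p, by = "taxon_id") %>%
    left_join(hub, by = "taxon_id") %>%
    mutate(z_norm = minmax(.data$within_module_z),
           p_norm = minmax(.data$participation),
           hub_norm = minmax(.data$hub),
           composite = (.data$z_norm + .data$p_norm + .data$hub_norm) / 3)
  out
}

#' Score every taxon node of a phenotype-taxon network
#'
#' Convenience wrapper: Walktrap modules on the taxon-taxon subgraph (the
#' phenotype node is excluded from modularity roles), within-module z,
#' participation, hub scores, and the composite.
#'
#' @param phona A `rhizo_phona`.
#' @param walk_steps Walktrap random-walk length.
#' @return The [composite_score()] tibble over the co-occurrence nodes.
#' @export
phona_node_scores <- function(phona, walk_steps = 4) {
  stopifnot(inherits(phona, "rhizo_phona"))
  net <- phona$taxa_network
  if (nrow(net$nodes) == 0) {
    return(tibble(taxon_id = character(), within_module_z = numeric(),
                  participation = numeric(), hub = numeric(),
                  z_norm = numeric(), p_norm = numeric(), hub_norm = numeric(),
                  composite = numeric()))
  }
  part <- walktrap_communities(net, walk_steps = walk_steps)
  hub <- hub_scores(net)
  if (nrow(hub) == 0) hub <- tibble(taxon_id = net$nodes$taxon_id, hub = 0)
  composite_score(within_module_z(net, part),
                  participation_coefficient(net, part),
                  hub)
}
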