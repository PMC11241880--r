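# The rhizo_network class: an undirected signed graph over taxa, stored as
# node and edge tibbles. Nodes are exactly the taxa incident to at least one
# retained edge; edges carry the association statistics that admitted them.

new_network <- function(edges, nodes = NULL, metadata = list()) {
  need <- c("taxon_i", "taxon_j", "coefficient", "p", "q", "sign")
  stopifnot(all(need %in% names(edges)))
  if (any(edges$taxon_i == edges$taxon_j)) abort("self-edges are not allowed")
  pair <- order_pair(edges$taxon_i, edges$taxon_j)
  edges$taxon_i <- pair$i
  edges$taxon_j <- pair$j
  edges <- edges %>% arrange(.data$taxon_i, .data$taxon_j)
  if (anyDuplicated(paste(edges$taxon_i, edges$taxon_j, sep = "\r"))) {
    abort("duplicate edges are not allowed")
  }
  if (is.null(nodes)) nodes <- tibble(taxon_id = sort(unique(c(edges$taxon_i, edges$taxon_j))))
  structure(list(nodes = nodes, edges = as_tibble(edges), metadata = metadata),
            class = "rhizo_network")
}

#' Build a co-occurrence network from association statistics
#'
#' Retains taxon pairs whose association magnitude exceeds `rho_threshold`
#' and whose BH-adjusted q-value falls below `q_threshold`. Nodes are the
#' endpoints of retained edges only: taxa without a significant association
#' are not network members. The result is invariant to the ordering of the
#' association list.
#'
#' @param assocs Output of [pairwise_associations()].
#' @param rho_threshold Minimum absolute coefficient (strict), default 0.6.
#' @param q_threshold Maximum q-value (strict), default 0.05.
#' @return A `rhizo_network`. [tidy()] returns the edge tibble, [glance()]
#'   the ten-metric topology summary.
#' @examples
#' assocs <- tibble::tibble(taxon_i = "a", taxon_j = "b",
#'                          coefficient = 0.9, p = 0.001, q = 0.01, sign = 1L)
#' build_network(assocs)
#' @export
build_network <- function(assocs, rho_threshold = 0.6, q_threshold = 0.05) {
  stopifnot(rho_threshold >= 0, q_threshold > 0)
  edges <- assocs %>%
    filter(abs(.data$coefficient) > rho_threshold, .data$q < q_threshold)
  new_network(edges, metadata = list(
    method = attr(assocs, "method") %||% NA_character_,
    rho_threshold = rho_threshold, q_threshold = q_threshold,
    n_tested = nrow(assocs)
  ))
}

#' @export
print.rhizo_network <- function(x, ...) {
  cat(sprintf("<rhizo_network> %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' @rdname build_network
#' @param x A `rhizo_network`.
#' @param ... Unused.
#' @method tidy rhizo_network
#' @export
tidy.rhizo_network <- function(x, ...) x$edges

#' @rdname build_network
#' @method glance rhizo_network
#' @export
glance.rhizo_network <- function(x, ...) summarize_topology(x)

# Convert to an igraph object (edge attributes preserved).
as_igraph <- function(net) {
  stopifnot(inherits(net, "rhizo_network"))
  igraph::graph_from_data_frame(
    d = net$edges %>% rename(from = "taxon_i", to = "taxon_j"),
    directed = FALSE,
    vertices = net$nodes %>% rename(name = "taxon_id")
  )
}

#' Write a network as an edge-list TSV and a GraphML document
#'
#' Emits `<path_prefix>.edges.tsv` (source, target, coefficient, p, q, sign)
#' and `<path_prefix>.graphml` carrying the same attributes. Empty networks
#' produce valid (header-only / zero-node) documents.
#'
#' @param net A `rhizo_network`.
#' @param path_prefix Output path without extension.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network <- function(net, path_prefix) {
  stopifnot(inherits(net, "rhizo_network"))
  edge_path <- paste0(path_prefix, ".edges.tsv")
  graphml_path <- paste0(path_prefix, ".graphml")
  net$edges %>%
    rename(source = "taxon_i", target = "taxon_j") %>%
    readr::write_tsv(edge_path)
  igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(c(edges = edge_path, graphml = graphml_path))
}

#' Read a network back from a GraphML document
#'
#' Round-trip companion to [write_network()].
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return A `rhizo_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble(taxon_id = igraph::V(g)$name)
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed) == 0) {
    edges <- tibble(taxon_i = character(), taxon_j = character(),
                    coefficient = numeric(), p = numeric(), q = numeric(),
                    sign = integer())
  } else {
    edges <- tibble(taxon_i = ed$from, taxon_j = ed$to,
                    coefficient = ed$coefficient, p = ed$p, q = ed$q,
                    sign = as.integer(ed$sign))
  }
  new_network(edges, nodes = nodes)
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout with edges colored by association sign.
#'
#' @param object A `rhizo_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhizo_network
#' @export
autoplot.rhizo_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes %>% mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges %>%
    left_join(nodes %>% select("taxon_id", xi = "x", yi = "y"),
              by = c(taxon_i = "taxon_id")) %>%
    left_join(nodes %>% select("taxon_id", xj = "x", yj = "y"),
              by = c(taxon_j = "taxon_id")) %>%
    mutate(sign = factor(ifelse(.data$sign > 0, "positive", "negative"),
                         levels = c("positive", "negative")))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xi, y = .data$yi,
                                       xend = .data$xj, yend = .data$yj,
                                       colour = .data$sign),
                          linewidth = 0.4, alpha = 0.7) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac", negative = "#b2182b"),
                                 drop = FALSE) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "association")
}
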