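test_that("degree centralization matches closed forms", {
  expect_equal(centralization_degree(fixture_graph("two_triangles")), 0)
  expect_equal(centralization_degree(fixture_graph("complete4")), 0)
  expect_equal(centralization_degree(fixture_graph("star4")), 1)
  expect_equal(centralization_degree(fixture_graph("path_n", n = 3)), 1)
  tiny <- edge_network("a", "b")
  expect_message(cz <- centralization_degree(tiny), "fewer than 3")
  expect_equal(cz, 0)
})

test_that("walktrap reaches the exhaustive-search modularity optimum on small graphs", {
  graphs <- list(
    fixture_graph("two_triangles"),
    fixture_graph("complete4"),
    fixture_graph("three_triangles"),
    # two triangles joined by a bridge
    edge_network(c("a", "a", "b", "c", "d", "d", "e"),
                 c("b", "c", "c", "d", "e", "f", "f"))
  )
  for (net in graphs) {
    part <- walktrap_communities(net)
    q_walk <- modularity_q(net, part)
    q_best <- max_modularity_oracle(net)
    expect_equal(q_walk, q_best, tolerance = 1e-12)
  }
  # forced partitions: each triangle is one community
  part <- walktrap_communities(fixture_graph("two_triangles"))
  expect_equal(dplyr::n_distinct(part$community), 2)
  expect_equal(dplyr::n_distinct(walktrap_communities(fixture_graph("complete4"))$community), 1)
})

test_that("distinct components never share a community", {
  net <- edge_network(c("a", "c", "e"), c("b", "d", "f"))
  part <- walktrap_communities(net)
  expect_equal(dplyr::n_distinct(part$community), 3)
})

test_that("modularity matches igraph and its closed forms", {
  t2 <- fixture_graph("two_triangles")
  part <- walktrap_communities(t2)
  expect_equal(modularity_q(t2, part), 0.5)
  t3 <- fixture_graph("three_triangles")
  expect_equal(modularity_q(t3, walktrap_communities(t3)), 1 - 1 / 3, tolerance = 1e-12)
  expect_equal(modularity_q(fixture_graph("complete4"),
                            walktrap_communities(fixture_graph("complete4"))), 0)
  # all-in-one partition has modularity 0 for any graph
  for (name in c("two_triangles", "star4", "complete4")) {
    net <- fixture_graph(name)
    one <- tibble::tibble(taxon_id = net$nodes$taxon_id, community = 1L)
    expect_equal(modularity_q(net, one), 0, tolerance = 1e-12)
  }
  # igraph cross-check on an irregular graph
  net <- edge_network(c("a", "a", "b", "c", "d"), c("b", "c", "c", "d", "e"))
  part <- walktrap_communities(net)
  g <- igraph::graph_from_data_frame(net$edges[1:2], directed = FALSE)
  memb <- part$community[match(igraph::V(g)$name, part$taxon_id)]
  expect_equal(modularity_q(net, part), igraph::modularity(g, memb), tolerance = 1e-12)
})

test_that("hub scores match eigen structure and igraph on connected graphs", {
  s4 <- hub_scores(fixture_graph("star4"))
  expect_equal(s4$hub[s4$taxon_id == "t01"], 1, tolerance = 1e-8)
  expect_equal(s4$hub[s4$taxon_id != "t01"], rep(1 / sqrt(3), 3), tolerance = 1e-8)
  # regular graphs: every node scores 1 (two triangles included)
  expect_equal(hub_scores(fixture_graph("two_triangles"))$hub, rep(1, 6), tolerance = 1e-8)
  expect_equal(hub_scores(fixture_graph("complete4"))$hub, rep(1, 4), tolerance = 1e-8)
  # irregular connected graph vs igraph's ARPACK implementation
  net <- edge_network(c("a", "a", "b", "c", "d"), c("b", "c", "c", "d", "e"))
  ours <- hub_scores(net)
  ig <- suppressWarnings(
    igraph::hub_score(as.data.frame(net$edges[1:2]) |>
                        igraph::graph_from_data_frame(directed = FALSE),
                      scale = TRUE)$vector)
  expect_equal(ours$hub, unname(ig[ours$taxon_id]), tolerance = 1e-6)
  # invariance to edge sign
  net_neg <- net
  net_neg$edges$coefficient <- -net_neg$edges$coefficient
  net_neg$edges$sign <- -net_neg$edges$sign
  expect_equal(hub_scores(net_neg)$hub, ours$hub)
})

test_that("hub counting uses a strict threshold", {
  expect_equal(hub_count(tibble::tibble(taxon_id = letters[1:3], hub = rep(1, 3))), 3)
  expect_equal(hub_count(rep(0.1, 5)), 0)
  expect_equal(hub_count(hub_scores(fixture_graph("star4"))), 4)
  expect_equal(hub_count(c(0.2, 0.2000001)), 1)
})

test_that("power-law fits are undefined for regular degree sequences", {
  expect_false(power_law_fit(rep(2, 6))$defined)
  expect_true(is.na(glance(fixture_graph("two_triangles"))$ks_stat))
  expect_true(power_law_fit(c(1, 1, 1, 2, 3, 5))$defined)
})

test_that("power-law KS statistic matches a brute-force CDF scan", {
  withr::with_seed(61, {
    for (rep in 1:3) {
      x <- rzeta(80, alpha = 2.3, xmax = 500)
      fit <- power_law_fit(x)
      tail_x <- x[x >= fit$xmin]
      support <- fit$xmin:max(tail_x)
      z <- sum((fit$xmin:100000)^(-fit$alpha))
      cdf_fit <- cumsum(support^(-fit$alpha) / z)
      cdf_emp <- sapply(support, function(v) mean(tail_x <= v))
      expect_equal(fit$ks_stat, max(abs(cdf_emp - cdf_fit)), tolerance = 1e-4)
    }
  })
})

test_that("power-law exponent recovery at n = 1000", {
  hits <- withr::with_seed(71, {
    sum(vapply(1:100, function(s) {
      x <- rzeta(1000, alpha = 2.5)
      fit <- power_law_fit(x)
      abs(fit$alpha - 2.5) <= 0.3
    }, logical(1)))
  })
  expect_gte(hits, 90)
})

test_that("friedman test matches its formula and a permutation null", {
  same <- matrix(rep(c(1, 5, 9), 2), ncol = 2)
  res <- friedman_rank_test(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  dominated <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  expect_equal(friedman_rank_test(dominated)$statistic, 3)
  expect_error(friedman_rank_test(cbind(c(1, NA), c(2, 3))), "missing")
  # chi-squared approximation roughly matches a permutation null on 3x3
  withr::with_seed(81, {
    m <- matrix(rnorm(9), 3, 3)
    obs <- friedman_rank_test(m)$statistic
    stat_perm <- replicate(2000, {
      mp <- t(apply(m, 1, sample))
      friedman_rank_test(mp)$statistic
    })
    p_perm <- mean(stat_perm >= obs - 1e-12)
    expect_lt(abs(p_perm - friedman_rank_test(m)$p.value), 0.15)
  })
})

test_that("topology identities hold on every reference network row", {
  for (method in c("spearman", "pearson")) {
    ref <- reference_topology(method)
    expect_equal(nrow(ref), 16)
    expect_equal(round2(2 * ref$edge_count / (ref$node_count * (ref$node_count - 1))),
                 ref$connectance)
    expect_equal(round2(2 * ref$edge_count / ref$node_count), ref$mean_degree)
  }
})
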