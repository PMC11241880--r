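test_that("spearman coefficients match the rank formula and brute force", {
  nt <- tibble::tibble(taxon_id = c("x", "y"),
                       S1 = c(1, 3), S2 = c(2, 1), S3 = c(3, 2), S4 = c(4, 4))
  # on the first three samples the classic d^2 formula gives -0.5; here use a
  # 4-sample table (minimum) and the brute-force oracle instead
  res <- pairwise_associations(nt)
  oracle <- cor(rank(c(1, 2, 3, 4)), rank(c(3, 1, 2, 4)))
  expect_equal(res$coefficient, oracle, tolerance = 1e-12)

  # vectorized output equals a double-loop cor() oracle on a 10 x 8 fixture
  ct <- random_count_table(n_taxa = 10, n_samples = 8, seed = 17, zero_prob = 0.1)
  for (method in c("spearman", "pearson")) {
    res <- pairwise_associations(ct, method)
    m <- as.matrix(ct[-1]); rownames(m) <- ct$taxon_id
    for (k in seq_len(nrow(res))) {
      expect_equal(res$coefficient[k],
                   cor(m[res$taxon_i[k], ], m[res$taxon_j[k], ], method = method),
                   tolerance = 1e-12)
    }
  }
})

test_that("monotone pairs give rho 1 and p 0; q dominates p", {
  nt <- tibble::tibble(taxon_id = c("a", "b", "c"),
                       S1 = c(1, 2, 5), S2 = c(2, 4, 1), S3 = c(3, 6, 2),
                       S4 = c(4, 8, 9), S5 = c(5, 10, 3))
  res <- pairwise_associations(nt)
  ab <- res[res$taxon_i == "a" & res$taxon_j == "b", ]
  expect_equal(ab$coefficient, 1)
  expect_equal(ab$p, 0)
  expect_true(all(res$q >= res$p))
})

test_that("zero-variance taxa are excluded from testing with a message", {
  nt <- tibble::tibble(taxon_id = c("flat", "a", "b"),
                       S1 = c(2, 1, 4), S2 = c(2, 2, 3), S3 = c(2, 3, 2),
                       S4 = c(2, 4, 1))
  expect_message(res <- pairwise_associations(nt), "flat")
  expect_false("flat" %in% c(res$taxon_i, res$taxon_j))
  expect_equal(nrow(res), 1)
})

test_that("BH adjustment matches the hand-worked step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  # order-preserving mapping back to input positions
  p <- c(0.04, 0.005, 0.03, 0.01)
  expect_equal(bh_fdr(p), c(0.04, 0.02, 0.04, 0.02))
})

test_that("network gating applies both thresholds and drops isolated taxa", {
  assocs <- tibble::tibble(
    taxon_i = c("a", "a", "b"), taxon_j = c("b", "c", "c"),
    coefficient = c(0.9, 0.65, -0.3), p = c(1e-4, 0.01, 0.2),
    q = c(1e-3, 0.2, 0.4), sign = c(1L, 1L, -1L))
  net <- build_network(assocs)
  expect_equal(nrow(net$edges), 1) # |rho| > 0.6 AND q < 0.05
  expect_setequal(net$nodes$taxon_id, c("a", "b"))
  # invariance to association-list ordering
  net2 <- build_network(assocs[c(3, 1, 2), ])
  expect_equal(net$edges, net2$edges)
  # nothing passes -> valid empty network
  empty <- build_network(assocs, rho_threshold = 0.99)
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(glance(empty)$node_count, 0L)
})

test_that("planted edges are recovered with high precision and recall", {
  pairs <- tibble::tibble(
    taxon_i = c("Euk_g001", "Euk_g003", "Prok_s001"),
    taxon_j = c("Euk_g002", "Euk_g004", "Prok_s002"),
    correlation = 0.9)
  planted <- paste(pairs$taxon_i, pairs$taxon_j)
  stats <- vapply(1:20, function(s) {
    cfg <- sim_config(n_taxa_euk = 15, n_taxa_prok = 15, planted_pairs = pairs,
                      prevalence_target = 1, seed = s)
    sim <- simulate_community(cfg)
    net <- build_network(pairwise_associations(css_normalize(sim$counts)))
    found <- paste(net$edges$taxon_i, net$edges$taxon_j)
    tp <- sum(planted %in% found)
    c(recall = tp / length(planted),
      precision = if (length(found)) tp / length(found) else 1)
  }, numeric(2))
  expect_gte(mean(stats["recall", ]), 0.9)
  expect_gte(mean(stats["precision", ]), 0.9)
})

test_that("without planted pairs, significant edges stay at the FDR level", {
  q_hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_taxa_euk = 10, n_taxa_prok = 10, prevalence_target = 1,
                      seed = 1000 + s)
    sim <- simulate_community(cfg)
    assocs <- pairwise_associations(css_normalize(sim$counts))
    sum(assocs$q < 0.05) / nrow(assocs)
  }, numeric(1))
  expect_lte(mean(q_hits), 0.05)
})
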