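make_phenotype_sim <- function(seed, effect_size = 2, noise_sd = 0.5,
                               n_taxa = 50) {
  cfg <- sim_config(n_taxa_euk = n_taxa, n_taxa_prok = 0,
                    prevalence_target = 1, seed = seed,
                    planted_effects = tibble::tibble(
                      phenotype = "pheno", taxon = "Euk_g005",
                      effect_size = effect_size, noise_sd = noise_sd))
  sim <- simulate_community(cfg)
  ph <- simulate_phenotypes(sim$counts, cfg, metadata = sim$metadata)$phenotypes
  list(counts = sim$counts, y = setNames(ph$value, ph$sample_id))
}

test_that("lasso recovers a planted phenotype taxon", {
  hits <- vapply(1:100, function(s) {
    dat <- make_phenotype_sim(seed = s)
    sel <- lasso_select(dat$counts, dat$y, seed = s)
    "Euk_g005" %in% sel$selected$taxon_id
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("lasso selects nothing under a pure-noise phenotype (median)", {
  sizes <- vapply(1:100, function(s) {
    cfg <- sim_config(n_taxa_euk = 50, n_taxa_prok = 0, prevalence_target = 1,
                      seed = s)
    sim <- simulate_community(cfg)
    y <- withr::with_seed(s + 500, rnorm(64))
    names(y) <- setdiff(names(sim$counts), "taxon_id")
    nrow(lasso_select(sim$counts, y, seed = s)$selected)
  }, numeric(1))
  expect_equal(median(sizes), 0)
})

test_that("constant phenotypes and duplicate predictors behave sanely", {
  ct <- random_count_table(n_taxa = 10, n_samples = 12, seed = 3)
  expect_warning(sel <- lasso_select(ct, rep(1, 12)), "constant")
  expect_equal(nrow(sel$selected), 0)
  # duplicated predictor columns never enter with opposite signs
  dup <- dplyr::bind_rows(ct, dplyr::mutate(ct[1, ], taxon_id = "tx01_copy"))
  y <- as.numeric(as.matrix(ct[1, -1])) * 2 + withr::with_seed(4, rnorm(12, sd = 0.1))
  sel2 <- suppressWarnings(lasso_select(dup, y, seed = 1))
  picked <- sel2$selected[sel2$selected$taxon_id %in% c("tx01", "tx01_copy"), ]
  if (nrow(picked) == 2) expect_equal(length(unique(sign(picked$coefficient))), 1)
})

test_that("the GLM stage reproduces closed-form OLS", {
  x <- c(1, 2, 3, 4, 5)
  nt <- tibble::tibble(taxon_id = "tx", !!!setNames(as.list(x), paste0("S", 1:5)))
  y <- 3 - 2 * x
  res <- suppressWarnings(fit_glm(nt, y, tibble::tibble(taxon_id = "tx", coefficient = -1)))
  expect_equal(res$estimate, -2, tolerance = 1e-12)
  expect_equal(res$sign, -1L)
  # y = x exactly
  res2 <- suppressWarnings(fit_glm(nt, x, tibble::tibble(taxon_id = "tx", coefficient = 1)))
  expect_equal(res2$estimate, 1, tolerance = 1e-12)
  # permutation of samples leaves the fit unchanged
  perm <- c(3, 1, 5, 2, 4)
  nt_p <- nt[c("taxon_id", paste0("S", perm))]
  res3 <- suppressWarnings(fit_glm(nt_p, y[perm], tibble::tibble(taxon_id = "tx", coefficient = -1)))
  expect_equal(res3$estimate, res$estimate)
})

test_that("phenotype-taxon network assembly is additive and never invents edges", {
  cooc <- edge_network(c("a", "a", "b"), c("b", "c", "c"))
  glm_edges <- tibble::tibble(taxon_id = "d", estimate = 1.5, sign = 1L,
                              p.value = 0.01)
  phona <- assemble_phona(cooc, glm_edges, "pH")
  expect_equal(nrow(tidy(phona)), 4) # 3 cooc + 1 phenotype edge
  expect_setequal(phona$nodes$taxon_id, c("a", "b", "c", "d"))
  expect_equal(glance(phona)$total_edges, 4)
  tt <- tidy(phona) |> dplyr::filter(type == "taxon-taxon")
  expect_true(all(paste(tt$from, tt$to) %in%
                    paste(cooc$edges$taxon_i, cooc$edges$taxon_j)))
  # empty selection -> isolated phenotype node, no error
  lonely <- assemble_phona(cooc, NULL, "pH")
  expect_equal(nrow(lonely$phenotype_edges), 0)
  expect_equal(sum(tidy(lonely)$type == "phenotype-taxon"), 0)
})

test_that("modularity roles match hand-computed values", {
  # star module: center degree 3, leaves 1; population sd sqrt(0.75)
  star <- fixture_graph("star4")
  one_module <- tibble::tibble(taxon_id = star$nodes$taxon_id, community = 1L)
  z <- within_module_z(star, one_module)
  expect_equal(z$within_module_z[z$taxon_id == "t01"], 1.5 / sqrt(0.75), tolerance = 1e-12)
  expect_equal(sum(z$within_module_z), 0, tolerance = 1e-12)
  # equal within-module degree -> all z zero
  t2 <- fixture_graph("two_triangles")
  part <- walktrap_communities(t2)
  expect_equal(within_module_z(t2, part)$within_module_z, rep(0, 6))
  # participation: all links inside own module -> 0
  expect_equal(participation_coefficient(t2, part)$participation, rep(0, 6))
  # node with links split equally across two modules -> 0.5
  net <- edge_network(c("hub", "hub"), c("m1", "m2"))
  part2 <- tibble::tibble(taxon_id = c("hub", "m1", "m2"), community = c(1L, 1L, 2L))
  pc <- participation_coefficient(net, part2)
  expect_equal(pc$participation[pc$taxon_id == "hub"], 0.5)
  # equal split over m modules -> 1 - 1/m
  m <- 4
  net4 <- edge_network(rep("hub", m), paste0("n", 1:m))
  part4 <- tibble::tibble(taxon_id = c("hub", paste0("n", 1:m)),
                          community = c(1L, seq_len(m) + 1L))
  pc4 <- participation_coefficient(net4, part4)
  expect_equal(pc4$participation[pc4$taxon_id == "hub"], 1 - 1 / m)
})

test_that("composite scores are equal-weight means of min-max normalized metrics", {
  z <- tibble::tibble(taxon_id = c("a", "b", "c"), within_module_z = c(2, -1, 0.5))
  p <- tibble::tibble(taxon_id = c("a", "b", "c"), participation = c(0.6, 0, 0.3))
  h <- tibble::tibble(taxon_id = c("a", "b", "c"), hub = c(1, 0.2, 0.6))
  cs <- composite_score(z, p, h)
  expect_equal(cs$composite[cs$taxon_id == "a"], 1)
  expect_equal(cs$composite[cs$taxon_id == "b"], 0)
  expect_equal(cs$composite[cs$taxon_id == "c"], 0.5)
  expect_true(all(cs$composite >= 0 & cs$composite <= 1))
  expect_equal(cs$composite, (cs$z_norm + cs$p_norm + cs$hub_norm) / 3, tolerance = 1e-12)
  # constant metric maps to 0.5 everywhere
  hc <- tibble::tibble(taxon_id = c("a", "b", "c"), hub = rep(0.7, 3))
  expect_equal(composite_score(z, p, hc)$hub_norm, rep(0.5, 3))
})

test_that("prioritization filters by prevalence before ranking", {
  scores <- list(net1 = tibble::tibble(taxon_id = c("rare", "mid", "low"),
                                       composite = c(1, 0.8, 0.2)),
                 net2 = tibble::tibble(taxon_id = c("rare", "mid"),
                                       composite = c(1, 0.6)))
  prev <- tibble::tibble(taxon_id = c("rare", "mid", "low"),
                         prevalence = c(0.1, 0.9, 0.5))
  rep <- prioritize(scores, prev, min_prevalence = 0.2, top_k = 20) |>
    suppressMessages()
  expect_false("rare" %in% rep$taxon_id)
  expect_equal(rep$taxon_id[1], "mid")
  expect_equal(rep$mean_composite[rep$taxon_id == "mid"], 0.7)
  expect_equal(rep$mean_composite_zero_filled[rep$taxon_id == "low"], 0.1)
  expect_equal(rep$n_networks[rep$taxon_id == "mid"], 2L)
  # top_k larger than survivor count returns the full list with a message
  expect_message(full <- prioritize(scores, prev, top_k = 20), "survive")
  expect_equal(nrow(full), 2)
})

test_that("a planted hub ranks first in the prioritization report", {
  spokes <- sprintf("Euk_g%03d", 2:7)
  lambda <- 0.75
  pairs <- dplyr::bind_rows(
    tibble::tibble(taxon_i = "Euk_g001", taxon_j = spokes, correlation = lambda),
    {
      cmb <- utils::combn(spokes, 2)
      tibble::tibble(taxon_i = cmb[1, ], taxon_j = cmb[2, ],
                     correlation = lambda^2)
    })
  ranks <- vapply(1:20, function(s) {
    cfg <- sim_config(n_taxa_euk = 30, n_taxa_prok = 0, prevalence_target = 1,
                      planted_pairs = pairs, seed = s,
                      planted_effects = tibble::tibble(
                        phenotype = "pheno", taxon = "Euk_g001",
                        effect_size = 2, noise_sd = 0.5))
    sim <- simulate_community(cfg)
    css <- css_normalize(sim$counts)
    net <- build_network(pairwise_associations(css))
    if (!"Euk_g001" %in% net$nodes$taxon_id) return(NA_integer_)
    ph <- simulate_phenotypes(sim$counts, cfg, metadata = sim$metadata)$phenotypes
    y <- setNames(ph$value, ph$sample_id)
    sel <- lasso_select(css, y, seed = s)
    glm_edges <- if (nrow(sel$selected)) fit_glm(css, y, sel$selected)
    phona <- assemble_phona(net, glm_edges, "pheno", prevalence = prevalence(sim$counts))
    sc <- phona_node_scores(phona)
    rep <- suppressMessages(prioritize(list(sc), prevalence(sim$counts)))
    rep$rank[rep$taxon_id == "Euk_g001"]
  }, integer(1))
  expect_gte(sum(ranks == 1, na.rm = TRUE), 18)
})

test_that("node-phenotype associations reuse the pairwise machinery", {
  ct <- random_count_table(n_taxa = 5, n_samples = 8, seed = 23, zero_prob = 0)
  counts <- as.numeric(as.matrix(ct[2, -1]))
  ph <- tibble::tibble(sample_id = rep(names(ct)[-1], 2),
                       phenotype = rep(c("mono", "flat"), each = 8),
                       value = c(log1p(counts), rep(1, 8)))
  expect_message(res <- node_phenotype_associations(ct, ph), "flat")
  mono <- res$taxon_phenotype |>
    dplyr::filter(taxon_id == ct$taxon_id[2], phenotype == "mono")
  expect_equal(mono$coefficient, 1)
  expect_true(all(res$taxon_phenotype$q >= res$taxon_phenotype$p))
  expect_equal(nrow(res$taxon_taxon), choose(5, 2))
})
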