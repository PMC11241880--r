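#' Configure the synthetic community generator
#'
#' Bundles and validates the parameters of the synthetic rhizosphere
#' community. Defaults emulate a 64-sample field trial: a 2 (treatment) x 2
#' (cultivar) x 4 (growth stage) factorial replicated across 4 field blocks,
#' with sparse zero-inflated counts for a eukaryote (genus-level) and a
#' prokaryote (species-level) domain.
#'
#' Counts are produced through a Gaussian copula: a latent multivariate normal
#' with the planted pairwise correlations (identity elsewhere), a shared
#' block-level offset of standard deviation `block_sd`, a probability-integral
#' transform, and inversion of a negative-binomial CDF (mean `nb_mean`,
#' dispersion/size `nb_dispersion`). An independent Bernoulli mask then thins
#' presences so the expected per-taxon prevalence equals `prevalence_target`.
#'
#' @param n_taxa_euk,n_taxa_prok Number of eukaryote / prokaryote taxa.
#' @param n_samples Number of samples; must be divisible by 16 so the
#'   treatment x cultivar x growth-stage factorial is balanced across blocks.
#' @param nb_mean,nb_dispersion Negative-binomial mean and size (dispersion)
#'   of the count marginals.
#' @param prevalence_target Expected fraction of samples in which a taxon is
#'   detected, in (0, 1]. A target of 1 disables the mask.
#' @param planted_pairs Data frame with columns `taxon_i`, `taxon_j`,
#'   `correlation` giving latent correlations in (-1, 1) to plant.
#' @param planted_effects Data frame with columns `phenotype`, `taxon`,
#'   `effect_size`, `noise_sd`: each phenotype is
#'   `sum(effect_size * log1p(count))` over its planted taxa, plus a block
#'   offset and Gaussian noise.
#' @param block_sd Standard deviation of the shared block-level latent offset
#'   (and of the block offset added to phenotypes).
#' @param seed Integer seed; every generator draw is a deterministic function
#'   of it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa_euk = 30, n_taxa_prok = 30, n_samples = 64,
                       nb_mean = 50, nb_dispersion = 0.5,
                       prevalence_target = 0.8,
                       planted_pairs = NULL, planted_effects = NULL,
                       block_sd = 0.3, seed = 1L) {
  stopifnot(n_taxa_euk >= 0, n_taxa_prok >= 0, n_taxa_euk + n_taxa_prok >= 1,
            nb_mean > 0, nb_dispersion > 0,
            prevalence_target > 0, prevalence_target <= 1, block_sd >= 0)
  if (n_samples %% 16 != 0 || n_samples < 16) {
    abort("n_samples must be a positive multiple of 16 (2 x 2 x 4 factorial across blocks)")
  }
  taxa <- sim_taxon_ids(n_taxa_euk, n_taxa_prok)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as_tibble(planted_pairs)
    stopifnot(all(c("taxon_i", "taxon_j", "correlation") %in% names(planted_pairs)))
    bad <- !(planted_pairs$taxon_i %in% taxa) | !(planted_pairs$taxon_j %in% taxa)
    if (any(bad)) abort(sprintf("planted pair references unknown taxa: %s",
                                paste(planted_pairs$taxon_i[bad], planted_pairs$taxon_j[bad],
                                      sep = "-", collapse = ", ")))
    if (any(planted_pairs$taxon_i == planted_pairs$taxon_j)) {
      abort("planted pairs must reference two distinct taxa")
    }
    if (any(abs(planted_pairs$correlation) >= 1)) {
      abort("planted latent correlations must lie strictly inside (-1, 1)")
    }
  }
  if (!is.null(planted_effects)) {
    planted_effects <- as_tibble(planted_effects)
    stopifnot(all(c("phenotype", "taxon", "effect_size", "noise_sd") %in% names(planted_effects)))
    bad <- !(planted_effects$taxon %in% taxa)
    if (any(bad)) abort(sprintf("planted effect references unknown taxa: %s",
                                paste(unique(planted_effects$taxon[bad]), collapse = ", ")))
  }
  structure(list(
    n_taxa_euk = as.integer(n_taxa_euk), n_taxa_prok = as.integer(n_taxa_prok),
    n_samples = as.integer(n_samples), nb_mean = nb_mean,
    nb_dispersion = nb_dispersion, prevalence_target = prevalence_target,
    planted_pairs = planted_pairs, planted_effects = planted_effects,
    block_sd = block_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

sim_taxon_ids <- function(n_euk, n_prok) {
  c(if (n_euk > 0) sprintf("Euk_g%03d", seq_len(n_euk)),
    if (n_prok > 0) sprintf("Prok_s%03d", seq_len(n_prok)))
}

# Planted latent correlation matrix; errors when not positive semi-definite.
sim_latent_sigma <- function(cfg, taxa) {
  p <- length(taxa)
  sigma <- diag(p)
  dimnames(sigma) <- list(taxa, taxa)
  if (!is.null(cfg$planted_pairs)) {
    for (k in seq_len(nrow(cfg$planted_pairs))) {
      i <- cfg$planted_pairs$taxon_i[k]
      j <- cfg$planted_pairs$taxon_j[k]
      sigma[i, j] <- sigma[j, i] <- cfg$planted_pairs$correlation[k]
    }
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      abort(sprintf(
        "planted correlation matrix is not positive semi-definite (min eigenvalue %.3g); offending pairs: %s",
        min(ev),
        paste(cfg$planted_pairs$taxon_i, cfg$planted_pairs$taxon_j, sep = "-", collapse = ", ")))
    }
  }
  sigma
}

#' Generate a synthetic community with planted correlation structure
#'
#' Draws a taxon-by-sample count table, balanced factorial metadata, taxon
#' annotations and a record of the planted truth from a [sim_config()].
#' Identical configurations (including the seed) give identical outputs.
#'
#' @param cfg A [sim_config()].
#' @return A list with `counts` (count tibble), `metadata`, `annotation`,
#'   and `truth` (planted pairs/effects, realized prevalence, seed).
#' @examples
#' sim <- simulate_community(sim_config(n_taxa_euk = 5, n_taxa_prok = 5, seed = 42))
#' dim(sim$counts)
#' @export
simulate_community <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  taxa <- sim_taxon_ids(cfg$n_taxa_euk, cfg$n_taxa_prok)
  md <- sim_metadata(cfg$n_samples)
  sigma <- sim_latent_sigma(cfg, taxa)
  p <- length(taxa); n <- cfg$n_samples
  m <- with_seed(cfg$seed, {
    ch <- chol(sigma + diag(1e-10, p))
    z <- matrix(rnorm(n * p), nrow = p) # taxa x samples, iid
    z <- crossprod(ch, z)               # planted correlations
    blocks <- unique(md$field_block)
    b <- setNames(rnorm(length(blocks), sd = cfg$block_sd), blocks)
    z <- sweep(z, 2, b[md$field_block], `+`)
    u <- pnorm(z)
    counts <- matrix(qnbinom(u, mu = cfg$nb_mean, size = cfg$nb_dispersion),
                     nrow = p, dimnames = list(taxa, md$sample_id))
    p_pos <- 1 - dnbinom(0, mu = cfg$nb_mean, size = cfg$nb_dispersion)
    keep_prob <- min(1, cfg$prevalence_target / p_pos)
    if (keep_prob < 1) {
      mask <- matrix(rbinom(n * p, 1, keep_prob), nrow = p)
      counts <- counts * mask
    }
    counts
  })
  ct <- matrix_to_ct(m)
  ct[-1] <- lapply(ct[-1], as.integer)
  ann <- tibble(
    taxon_id = taxa,
    domain = c(rep("eukaryote", cfg$n_taxa_euk), rep("prokaryote", cfg$n_taxa_prok)),
    rank = c(rep("genus", cfg$n_taxa_euk), rep("species", cfg$n_taxa_prok)),
    lifestyle = rep_len(c("saprotroph", "plant pathogen", "mutualist", "unknown"),
                        length(taxa))
  )
  truth <- list(
    planted_pairs = cfg$planted_pairs,
    planted_effects = cfg$planted_effects,
    prevalence = prevalence(ct),
    seed = cfg$seed
  )
  list(counts = ct, metadata = md, annotation = ann, truth = truth)
}

# Balanced 2 x 2 x 4 factorial across 4 blocks; deterministic assignment.
sim_metadata <- function(n_samples) {
  reps <- n_samples / 16L
  # One full factorial (16 combos) per 16 samples, cycling blocks B1..B4.
  combos <- tidyr::expand_grid(
    treatment = c("control", "biostimulant"),
    cultivar = c("CV1", "CV2"),
    growth_stage = c("V1", "V6", "R2", "R6")
  )
  md <- purrr::map_dfr(seq_len(reps), function(r) {
    combos %>% mutate(field_block = sprintf("B%d", (r - 1L) %% 4L + 1L))
  })
  md %>%
    mutate(sample_id = sprintf("S%03d", row_number()),
           growth_stage = factor(.data$growth_stage, levels = c("V1", "V6", "R2", "R6"),
                                 ordered = TRUE)) %>%
    select("sample_id", "treatment", "cultivar", "growth_stage", "field_block") %>%
    arrange(.data$sample_id)
}

#' Generate phenotypes with planted taxon effects
#'
#' Each configured phenotype is a linear combination of `log1p` counts of its
#' planted taxa plus a block-level offset (sd `block_sd`) and Gaussian noise.
#'
#' @param ct Count tibble from [simulate_community()].
#' @param cfg The same [sim_config()]; its `planted_effects` define the
#'   phenotypes. When `NULL`, a single pure-noise phenotype is produced.
#' @param metadata Sample metadata (for block assignment); defaults to the
#'   deterministic factorial implied by the sample count.
#' @return A list with `phenotypes` (long tibble: sample_id, phenotype,
#'   value) and `truth` (the planted effects and seed).
#' @export
simulate_phenotypes <- function(ct, cfg, metadata = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  samples <- ct_samples(ct)
  if (is.null(metadata)) metadata <- sim_metadata(length(samples))
  stopifnot(setequal(metadata$sample_id, samples))
  eff <- cfg$planted_effects
  if (is.null(eff)) {
    eff <- tibble(phenotype = "noise", taxon = ct$taxon_id[1],
                  effect_size = 0, noise_sd = 1)
  }
  m <- ct_matrix(ct)
  blocks <- metadata$field_block[match(samples, metadata$sample_id)]
  ph <- with_seed(cfg$seed + 1L, {
    purrr::map_dfr(unique(eff$phenotype), function(name) {
      rows <- eff[eff$phenotype == name, ]
      bad <- setdiff(rows$taxon, rownames(m))
      if (length(bad)) abort(sprintf("planted effect references unknown taxa: %s",
                                     paste(bad, collapse = ", ")))
      signal <- colSums(rows$effect_size * log1p(m[rows$taxon, , drop = FALSE]))
      b <- setNames(rnorm(length(unique(blocks)), sd = cfg$block_sd), unique(blocks))
      noise <- rnorm(length(samples), sd = rows$noise_sd[1])
      tibble(sample_id = samples, phenotype = name,
             value = as.numeric(signal) + b[blocks] + noise)
    })
  })
  list(phenotypes = ph %>% arrange(.data$phenotype, .data$sample_id),
       truth = list(planted_effects = cfg$planted_effects, seed = cfg$seed))
}

#' Small forced-structure fixture graphs
#'
#' Named graphs whose topology metrics are known in closed form: disjoint
#' triangles, the complete graph on four nodes, a star, and a path. Useful for
#' validating the topology suite against hand-computable values.
#'
#' @param name One of `"two_triangles"`, `"three_triangles"`, `"complete4"`,
#'   `"star4"`, `"path_n"`.
#' @param n Path length (nodes) when `name = "path_n"`.
#' @return A `rhizo_network`.
#' @examples
#' glance(fixture_graph("two_triangles"))
#' @export
fixture_graph <- function(name = c("two_triangles", "three_triangles",
                                   "complete4", "star4", "path_n"), n = 5) {
  name <- match.arg(name)
  tri <- function(offset) {
    v <- sprintf("t%02d", offset + 1:3)
    tibble(taxon_i = v[c(1, 1, 2)], taxon_j = v[c(2, 3, 3)])
  }
  edges <- switch(name,
    two_triangles = bind_rows(tri(0), tri(3)),
    three_triangles = bind_rows(tri(0), tri(3), tri(6)),
    complete4 = {
      v <- sprintf("t%02d", 1:4)
      cmb <- combn(v, 2)
      tibble(taxon_i = cmb[1, ], taxon_j = cmb[2, ])
    },
    star4 = tibble(taxon_i = "t01", taxon_j = sprintf("t%02d", 2:4)),
    path_n = {
      stopifnot(n >= 2)
      v <- sprintf("t%02d", seq_len(n))
      tibble(taxon_i = v[-n], taxon_j = v[-1])
    }
  )
  edges <- edges %>%
    mutate(coefficient = 1, p = 0, q = 0, sign = 1L)
  new_network(edges, metadata = list(source = paste0("fixture:", name)))
}
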