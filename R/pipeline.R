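#' Configure an end-to-end pipeline run
#'
#' Bundles stage parameters and thresholds for [run_pipeline()]. Inputs are
#' either a [sim_config()] (synthetic run) or paths to count/metadata/
#' phenotype TSVs.
#'
#' @param simulation A [sim_config()], or `NULL` when reading from files.
#' @param counts_path,metadata_path,phenotypes_path Input TSV paths (ignored
#'   when `simulation` is given; `phenotypes_path` optional).
#' @param out_dir Output directory (created if needed).
#' @param method Association method for the co-occurrence network.
#' @param css_quantile,scale_to CSS parameters.
#' @param rho_threshold,q_threshold Network gating thresholds.
#' @param hub_threshold,walk_steps Topology parameters.
#' @param core_threshold Core-taxon prevalence threshold.
#' @param min_prevalence,top_k Prioritization parameters.
#' @param permanova_metric,permanova_group,permanova_strata,n_perm PERMANOVA
#'   stage parameters.
#' @param lasso_folds Cross-validation folds for phenotype selection.
#' @param seed Global seed; expanded into per-stage seeds recorded in the
#'   manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, counts_path = NULL,
                            metadata_path = NULL, phenotypes_path = NULL,
                            out_dir = tempfile("rhizonet_run_"),
                            method = c("spearman", "pearson"),
                            css_quantile = 0.5, scale_to = 1000,
                            rho_threshold = 0.6, q_threshold = 0.05,
                            hub_threshold = 0.2, walk_steps = 4,
                            core_threshold = 0.5, min_prevalence = 0.2,
                            top_k = 20,
                            permanova_metric = "bray_curtis",
                            permanova_group = "treatment",
                            permanova_strata = "field_block",
                            n_perm = 999, lasso_folds = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(rho_threshold >= 0, rho_threshold <= 1, q_threshold > 0,
            q_threshold <= 1, hub_threshold >= 0, hub_threshold <= 1,
            core_threshold >= 0, core_threshold <= 1,
            min_prevalence >= 0, min_prevalence <= 1, top_k >= 1, n_perm >= 1)
  if (is.null(simulation) && (is.null(counts_path) || is.null(metadata_path))) {
    abort("either a simulation config or counts_path + metadata_path is required")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

# Per-stage seed substream: deterministic in (seed, stage index), < 2^31.
stage_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate/read, align, CSS-normalize,
#' alpha diversity, PERMANOVA, membership, associations, network, topology,
#' phenotype-taxon networks, prioritization — writing every intermediate
#' artifact under `cfg$out_dir` plus a JSON manifest recording the package
#' version, thresholds, per-stage seeds and MD5 hashes of all outputs. A
#' failing stage aborts with the stage name.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_tsv(obj, p)
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # -- inputs ---------------------------------------------------------------
  ph <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- stage("simulate", {
      scfg <- cfg$simulation
      scfg$seed <- stage_seed(cfg$seed, 1L)
      class(scfg) <- "sim_config"
      simulate_community(scfg)
    })
    ct <- sim$counts; md <- sim$metadata
    ph <- stage("simulate_phenotypes", {
      scfg <- cfg$simulation
      scfg$seed <- stage_seed(cfg$seed, 1L)
      class(scfg) <- "sim_config"
      simulate_phenotypes(ct, scfg, metadata = md)$phenotypes
    })
  } else {
    ct <- stage("read_counts", read_count_table(cfg$counts_path))
    md <- stage("read_metadata", read_sample_metadata(cfg$metadata_path))
    if (!is.null(cfg$phenotypes_path)) {
      ph <- stage("read_phenotypes", read_phenotype_table(cfg$phenotypes_path))
    }
  }
  aligned <- stage("align", align_tables(ct, md, ph))
  ct <- aligned$counts; md <- aligned$metadata; ph <- aligned$phenotypes
  emit(ct, "counts.tsv"); emit(md, "metadata.tsv")
  if (!is.null(ph)) emit(ph, "phenotypes.tsv")

  # -- normalization & diversity -------------------------------------------
  css <- stage("normalize", css_normalize(ct, cfg$css_quantile, cfg$scale_to))
  emit(css, "css_normalized.tsv")
  div <- stage("diversity", alpha_diversity(ct))
  emit(div, "alpha_diversity.tsv")
  perm <- stage("permanova", {
    dm <- dissimilarity(css, cfg$permanova_metric)
    strata <- if (!is.null(cfg$permanova_strata)) md[[cfg$permanova_strata]]
    permanova(dm, md[[cfg$permanova_group]], strata = strata,
              n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, 2L))
  })
  emit(glance(perm), "permanova.tsv")

  # -- membership -----------------------------------------------------------
  prev <- prevalence(ct)
  emit(prev, "prevalence.tsv")
  emit(core_taxa(relative_abundance(ct), cfg$core_threshold), "core_taxa.tsv")

  # -- co-occurrence network ------------------------------------------------
  assoc <- stage("associations", pairwise_associations(css, cfg$method))
  net <- stage("network", build_network(assoc, cfg$rho_threshold, cfg$q_threshold))
  net_paths <- write_network(net, file.path(cfg$out_dir, "network"))
  paths[["network.edges.tsv"]] <- net_paths[["edges"]]
  paths[["network.graphml"]] <- net_paths[["graphml"]]
  topo <- stage("topology", summarize_topology(net, cfg$hub_threshold, cfg$walk_steps))
  emit(topo, "topology.tsv")

  # -- phenotype-taxon networks & prioritization ----------------------------
  report <- NULL
  if (!is.null(ph) && nrow(net$edges) > 0) {
    scores <- list()
    for (pn in sort(unique(ph$phenotype))) {
      phona <- stage(paste0("phona:", pn), {
        yv <- ph %>% filter(.data$phenotype == pn)
        y <- setNames(yv$value, yv$sample_id)
        sel <- lasso_select(css, y, n_folds = cfg$lasso_folds,
                            seed = stage_seed(cfg$seed, 3L))
        glm_edges <- if (nrow(sel$selected) > 0) fit_glm(css, y, sel$selected)
        assemble_phona(net, glm_edges, pn, prevalence = prev)
      })
      emit(tidy(phona), sprintf("phona_%s.edges.tsv", pn))
      sc <- phona_node_scores(phona, cfg$walk_steps)
      emit(sc, sprintf("phona_%s.scores.tsv", pn))
      scores[[pn]] <- sc
    }
    report <- stage("prioritize",
                    prioritize(scores, prev, cfg$min_prevalence, cfg$top_k))
    emit(report, "prioritization.tsv")
  }

  manifest <- list(
    package = "rhizonet",
    version = as.character(utils::packageVersion("rhizonet")),
    seed = cfg$seed,
    stage_seeds = list(simulate = stage_seed(cfg$seed, 1L),
                       permanova = stage_seed(cfg$seed, 2L),
                       lasso = stage_seed(cfg$seed, 3L)),
    thresholds = cfg[c("method", "css_quantile", "rho_threshold", "q_threshold",
                       "hub_threshold", "walk_steps", "core_threshold",
                       "min_prevalence", "top_k", "n_perm")],
    outputs = lapply(paths, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
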