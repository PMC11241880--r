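#' Lasso selection of phenotype-predictive taxa
#'
#' L1-penalized linear regression of a phenotype on taxon abundances, with
#' the penalty chosen at the minimum of the k-fold cross-validated mean
#' squared error (fold assignment is seed-controlled, so selection is
#' reproducible). Predictors are standardized internally. Taxa with nonzero
#' coefficients at the chosen penalty are "selected".
#'
#' @param nt Abundance tibble (taxa in rows, samples in columns).
#' @param y Named numeric vector of phenotype values (names = sample ids), or
#'   unnamed in the column order of `nt`.
#' @param n_folds Cross-validation folds, default 5.
#' @param seed Integer seed for fold assignment.
#' @return A `rhizo_lasso` object: `selected` (tibble `taxon_id`,
#'   `coefficient`), `lambda`, `n_folds`, `seed`. Constant phenotypes yield an
#'   empty selection with a warning.
#' @export
lasso_select <- function(nt, y, n_folds = 5, seed = 1L) {
  validate_count_table(nt, integer_counts = FALSE)
  samples <- ct_samples(nt)
  if (!is.null(names(y))) {
    missing_s <- setdiff(samples, names(y))
    if (length(missing_s)) abort(sprintf("phenotype missing for sample(s): %s",
                                         paste(missing_s, collapse = ", ")))
    y <- y[samples]
  }
  if (length(y) != length(samples)) abort("y must have one value per sample")
  if (length(samples) < 8) abort("lasso_select needs at least 8 samples")
  x <- t(ct_matrix(nt)) # samples x taxa
  empty <- function() {
    structure(list(selected = tibble(taxon_id = character(), coefficient = numeric()),
                   lambda = NA_real_, n_folds = n_folds, seed = seed),
              class = "rhizo_lasso")
  }
  if (stats::var(y) == 0) {
    warn("constant phenotype: no taxa selected")
    return(empty())
  }
  keep <- apply(x, 2, function(v) stats::var(v) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < 2) {
    warn("fewer than two variable taxa: no taxa selected")
    return(empty())
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), length(y))))
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, foldid = folds, standardize = TRUE)
  b <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  sel <- b[b != 0]
  structure(list(
    selected = tibble(taxon_id = names(sel), coefficient = unname(sel)) %>%
      arrange(desc(abs(.data$coefficient))),
    lambda = cv$lambda.min, n_folds = n_folds, seed = seed
  ), class = "rhizo_lasso")
}

#' @export
print.rhizo_lasso <- function(x, ...) {
  cat(sprintf("<rhizo_lasso> %d taxa selected at lambda = %.4g\n",
              nrow(x$selected), x$lambda))
  invisible(x)
}

#' @rdname lasso_select
#' @param x A `rhizo_lasso` object.
#' @param ... Unused.
#' @method tidy rhizo_lasso
#' @export
tidy.rhizo_lasso <- function(x, ...) x$selected

#' @rdname lasso_select
#' @method glance rhizo_lasso
#' @export
glance.rhizo_lasso <- function(x, ...) {
  tibble(n_selected = nrow(x$selected), lambda = x$lambda,
         n_folds = x$n_folds, seed = x$seed)
}

#' Gaussian GLM over the lasso-selected taxa
#'
#' Ordinary least squares with intercept (identity-link Gaussian GLM) of the
#' phenotype on the selected taxa, providing the sign and a two-sided t-test
#' p-value per taxon. Collinear columns are dropped (R's pivoting rule); when
#' there are at least as many selected taxa as samples, selection is
#' truncated to the strongest lasso coefficients first (with a message).
#'
#' @param nt Abundance tibble.
#' @param y Phenotype values (named by sample or in column order).
#' @param selected Tibble `taxon_id`, `coefficient` (from [lasso_select()]).
#' @return A tibble `taxon_id`, `estimate`, `sign`, `p.value` (dropped
#'   collinear taxa carry `NA` estimates).
#' @export
fit_glm <- function(nt, y, selected) {
  validate_count_table(nt, integer_counts = FALSE)
  samples <- ct_samples(nt)
  if (!is.null(names(y))) y <- y[samples]
  stopifnot(length(y) == length(samples))
  if (nrow(selected) == 0) abort("fit_glm requires a non-empty selection")
  sel <- selected %>% arrange(desc(abs(.data$coefficient)))
  if (nrow(sel) >= length(samples) - 1) {
    keep_n <- length(samples) - 2L
    inform(sprintf("truncating selection from %d to %d taxa to keep the GLM identifiable",
                   nrow(sel), keep_n))
    sel <- sel %>% slice_head(n = keep_n)
  }
  m <- ct_matrix(nt)
  missing_t <- setdiff(sel$taxon_id, rownames(m))
  if (length(missing_t)) abort(sprintf("selected taxa absent from table: %s",
                                       paste(missing_t, collapse = ", ")))
  x <- t(m[sel$taxon_id, , drop = FALSE])
  dat <- as.data.frame(x)
  names(dat) <- sel$taxon_id
  fit <- lm(y ~ ., data = cbind(y = as.numeric(y), dat))
  sm <- summary(fit)$coefficients
  out <- tibble(taxon_id = sel$taxon_id,
                estimate = unname(coef(fit)[sel$taxon_id])) %>%
    mutate(sign = as.integer(sign(.data$estimate)),
           p.value = sm[match(.data$taxon_id, rownames(sm)), "Pr(>|t|)"])
  out
}

#' Assemble a phenotype-taxon network
#'
#' Overlays GLM-signed phenotype edges on a taxon co-occurrence network: the
#' node set is the union of the co-occurrence nodes, the selected taxa, and
#' one phenotype node; taxon-taxon edges are copied verbatim from the
#' co-occurrence network (never invented), and one phenotype-taxon edge per
#' selected taxon carries the GLM coefficient, sign and p-value. An empty
#' selection yields an isolated phenotype node.
#'
#' @param cooc A `rhizo_network` of taxon co-occurrences.
#' @param glm_edges Tibble from [fit_glm()] (or zero-row tibble).
#' @param phenotype_name Name of the phenotype node.
#' @param prevalence Optional tibble `taxon_id`, `prevalence` attached to the
#'   taxa for downstream filtering.
#' @return A `rhizo_phona` object with `taxa_network`, `phenotype`,
#'   `phenotype_edges`, `nodes`.
#' @export
assemble_phona <- function(cooc, glm_edges, phenotype_name, prevalence = NULL) {
  stopifnot(inherits(cooc, "rhizo_network"))
  if (is.null(glm_edges)) {
    glm_edges <- tibble(taxon_id = character(), estimate = numeric(),
                        sign = integer(), p.value = numeric())
  }
  taxa <- sort(unique(c(cooc$nodes$taxon_id, glm_edges$taxon_id)))
  nodes <- tibble(taxon_id = taxa)
  if (!is.null(prevalence)) nodes <- nodes %>% left_join(prevalence, by = "taxon_id")
  structure(list(
    taxa_network = cooc,
    phenotype = phenotype_name,
    phenotype_edges = as_tibble(glm_edges),
    nodes = nodes
  ), class = "rhizo_phona")
}

#' @export
print.rhizo_phona <- function(x, ...) {
  cat(sprintf("<rhizo_phona> phenotype '%s': %d taxa, %d taxon-taxon edges, %d phenotype edges\n",
              x$phenotype, nrow(x$nodes), nrow(x$taxa_network$edges),
              nrow(x$phenotype_edges)))
  invisible(x)
}

#' @rdname assemble_phona
#' @param x A `rhizo_phona` object.
#' @param ... Unused.
#' @method tidy rhizo_phona
#' @export
tidy.rhizo_phona <- function(x, ...) {
  bind_rows(
    x$taxa_network$edges %>%
      select(from = "taxon_i", to = "taxon_j", "coefficient", "p", "sign") %>%
      mutate(type = "taxon-taxon"),
    x$phenotype_edges %>%
      mutate(from = x$phenotype, type = "phenotype-taxon") %>%
      select("from", to = "taxon_id", coefficient = "estimate", p = "p.value",
             "sign", "type")
  )
}

#' @rdname assemble_phona
#' @method glance rhizo_phona
#' @export
glance.rhizo_phona <- function(x, ...) {
  tibble(phenotype = x$phenotype, n_taxa = nrow(x$nodes),
         n_taxon_edges = nrow(x$taxa_network$edges),
         n_phenotype_edges = nrow(x$phenotype_edges),
         total_edges = nrow(x$taxa_network$edges) + nrow(x$phenotype_edges))
}

#' Plot a phenotype-taxon network
#'
#' Taxon-taxon edges in grey, phenotype edges colored by GLM sign, the
#' phenotype node drawn as a square.
#'
#' @param object A `rhizo_phona`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rhizo_phona
#' @export
autoplot.rhizo_phona <- function(object, seed = 1L, ...) {
  edges <- tidy(object)
  ids <- unique(c(object$nodes$taxon_id, object$phenotype))
  g <- igraph::graph_from_data_frame(edges[c("from", "to")], directed = FALSE,
                                     vertices = data.frame(name = ids))
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- tibble(id = ids, x = xy[, 1], y = xy[, 2],
                  kind = ifelse(ids == object$phenotype, "phenotype", "taxon"))
  edges <- edges %>%
    left_join(nodes %>% select("id", xi = "x", yi = "y"), by = c(from = "id")) %>%
    left_join(nodes %>% select("id", xj = "x", yj = "y"), by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xi, y = .data$yi,
                                       xend = .data$xj, yend = .data$yj,
                                       colour = .data$type),
                          linewidth = 0.4, alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$kind), size = 2) +
    ggplot2::scale_shape_manual(values = c(taxon = 16, phenotype = 15)) +
    ggplot2::theme_void()
}
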