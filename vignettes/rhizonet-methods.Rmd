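---
title: "Methods and design of the rhizonet analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the rhizonet analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

`rhizonet` implements an analysis chain for rhizosphere microbiome count
data: normalization and diversity, distance-based hypothesis tests with
block-restricted permutations, statistically gated co-occurrence networks
with a ten-metric topology characterization, and phenotype–taxon networks
with composite-centrality prioritization. This vignette documents the models,
the tunable parameters, the synthetic-data generator that stands in for field
samples, and the numerical and design choices that were genuinely open.

## Input model and conventions

The unit of observation is a taxon-by-sample table of non-negative integer
counts (amplicon sequence variants conglomerated to genus or species level in
typical use), accompanied by per-sample metadata (treatment, cultivar,
ordered growth stage, field block) and a long table of continuous phenotype
measurements (edaphic chemistry, enzyme activities, agronomic traits).
Samples are always processed in lexicographic identifier order, so every
matrix, distance object and permutation stream is deterministic regardless of
input ordering. Raw counts and normalized abundances are kept in tables of
the same shape but are never mixed: normalization preserves zeros, and
presence/absence quantities (prevalence, Jaccard, uniqueness) are therefore
identical on either.

## Normalization and diversity

Cumulative sum scaling divides each sample's counts by the cumulative sum of
its counts up to a quantile of the *positive* counts, then rescales to a
common constant (default 1000). The quantile is fixed at `l = 0.5` with the
nearest-rank rule `ceil(l · n_pos)` rather than an adaptive instability
search: the adaptive variant is under-specified for the small tables used in
testing, and a fixed, documented quantile makes runs reproducible. The
scaling factor uses `counts ≤ q` (zeros included, which contribute nothing),
so a sample of k equal counts normalizes to `scale_to / k` per detected
taxon.

Chao1 uses the bias-corrected form `S_obs + f₁(f₁−1)/(2(f₂+1))` so the
estimate is defined when no doubletons are observed and never falls below
observed richness; all-zero samples return `NA` rather than an error.
Shannon entropy is reported in nats; Simpson diversity is `1 − Σ p²`; Pielou
evenness `H/ln S_obs` is undefined (NA) for single-taxon samples.

Distances: Bray–Curtis and Euclidean act on abundances; Jaccard acts on
presence/absence (the abundance-weighted variant is a defensible alternative;
the binary form is the one implemented and is recorded in the distance
object's `metric` attribute). A pair of all-zero samples has no defined
Bray–Curtis or Jaccard distance; it is set to 0 with a warning rather than
propagating NA, since two empty samples are trivially identical.

## PERMANOVA with restricted permutations

The test is the classic one-factor decomposition on squared distances, with
`SS_total = Σ_{i<j} d²_ij / n`, within-group sums weighted by group size,
and `pseudo-F = (SS_B/(a−1)) / (SS_W/(n−a))`. The p-value is the
add-one permutation estimator `(1 + #{F* ≥ F}) / (1 + n_perm)`, which can
never be exactly zero; 9,999 permutations is the default. When a stratum
factor (field block) is supplied, labels are shuffled only within strata —
the appropriate null when spatial heterogeneity makes samples exchangeable
only within a block. Degenerate designs with `SS_W = 0` report an infinite F
with the permutation p-value rather than crashing. Multi-factor models with
interactions are exercised by testing one factor at a time; a full
multi-factor partitioning is out of scope. `vegan::adonis2` is used in the
test suite as an independent oracle for the pseudo-F and R², and complete
enumeration of label permutations as the oracle for the p-value at small n.

SIMPER decomposes the mean between-group Bray–Curtis dissimilarity exactly:
per between-group sample pair, taxon i contributes
`|x_ij − x_ik| / Σ_t (x_tj + x_tk)`, and contributions are averaged over
pairs, so their sum equals the mean between-group dissimilarity to machine
precision (asserted at 1e-10 in the tests). The per-taxon permutation
p-value shares the add-one estimator.

## Co-occurrence networks

Associations are computed for every unordered taxon pair on CSS-normalized
abundances: Spearman as the product-moment correlation of average ranks, or
Pearson directly. Two-sided p-values use the t approximation with `n − 2`
degrees of freedom; the Benjamini–Hochberg adjustment is applied within each
run's own association set (global or condition-specific), and the scope is
recorded in the network metadata. Zero-variance taxa cannot be ranked against
anything and are excluded from testing with a message rather than producing
NAs. Edges require `|ρ| > 0.6` *and* `q < 0.05`; since `q ≥ p` elementwise, a
separate `p < 0.05` screen is redundant and both orderings give identical
edge sets. Nodes are the endpoints of retained edges only — taxa with no
significant association are not network members, which is what makes the
degenerate condition-specific networks (six nodes, six edges, two components)
uniquely forced structures. Edge signs are stored and displayed but ignored
by every topology metric, which describe the combined signed network.

### Topology metrics

* **Freeman degree centralization** `Σ(d_max − d_i)/((N−1)(N−2))`; 0 by
  convention (with a message) below three nodes.
* **Cluster count / giant component** from connected components.
* **Connectance** `2E/(N(N−1))` and **mean degree** `2E/N`.
* **Walktrap modularity**: communities from 4-step random-walk agglomeration
  applied independently per connected component (so components never share a
  community), cutting each component's merge tree at maximum Newman–Girvan
  modularity; `Q = Σ_c [m_c/m − (D_c/2m)²]` over the whole graph. Edgeless
  graphs have undefined Q. The test suite checks the partition against
  exhaustive enumeration of all node partitions on small graphs.
* **Hub scores and hub count**: Kleinberg's HITS hub vector. On an undirected
  graph the hub and authority vectors coincide with the principal eigenvector
  of the adjacency matrix. It is computed by power iteration on the
  Perron-shifted matrix `I + A` from the uniform vector with sup-norm
  scaling (tolerance 1e-10): the shift guarantees convergence on bipartite
  components, where iteration on `A²` has a degenerate dominant eigenspace
  and would not resolve the star graph's center/leaf distinction, and the
  uniform start yields the symmetric all-ones limit on graphs with
  interchangeable components (all six nodes of two disjoint triangles score
  1). Nodes with score strictly above 0.2 are hubs.
* **Power-law degree fit**: discrete maximum likelihood with a zeta
  normalizer — for each candidate `xmin` the exponent maximizes the tail
  likelihood, and the retained `xmin` minimizes the KS distance between
  empirical and fitted CDFs. The generalized zeta is computed by direct tail
  summation with an Euler–Maclaurin remainder, which avoids the catastrophic
  cancellation of `ζ(a) − partial sum` at large `xmin` or steep exponents.
  Degree sequences with fewer than two distinct values (regular graphs) have
  no meaningful fit and report "undefined" rather than NaN.
* **Friedman rank-sum test** compares the ranking of association methods
  across matched conditions; a fully tied matrix carries no ranking
  information and reports statistic 0, p = 1.

## Phenotype–taxon networks and prioritization

Taxa predictive of a phenotype are selected by lasso with the penalty at the
cross-validated MSE minimum (`lambda.min`, 5 folds, seed-controlled fold
assignment). The minimum-MSE rule rather than the 1-SE rule is a deliberate
choice: selection feeds a descriptive network overlay, not a sparse final
model, so the mildly more inclusive rule is preferred; the seeded folds make
it reproducible. A Gaussian identity-link GLM (ordinary least squares) on the
selected taxa provides each phenotype edge's coefficient, sign and two-sided
t-test p-value — the phenotypes are continuous chemistry/agronomy measures,
for which the Gaussian family is the natural default. When selection is not
identifiable (taxa ≥ samples), it is truncated to the strongest lasso
coefficients with a message.

The phenotype node is overlaid on the co-occurrence network: taxon–taxon
edges are copied verbatim (never invented), and an empty selection produces
an isolated phenotype node rather than an error. Modularity roles are
computed on the taxon–taxon subgraph only — the phenotype node describes the
measurement, not microbial structure. Within-module degree z-scores use the
module's *population* standard deviation with `z = 0` for degenerate
(constant or singleton) modules, the Guimerà–Amaral convention; the
participation coefficient is `1 − Σ_s (κ_is/k_i)²` with `P = 0` for isolated
nodes. The composite score min–max normalizes z, P and the hub score across
the network's nodes and averages them with equal weights; a metric that is
constant across the network is uninformative and maps to 0.5 for every node
rather than pushing all nodes to an extreme.

Prioritization filters to taxa with prevalence ≥ 0.2 *before* ranking (a
perfectly central but rare taxon is excluded), then ranks by mean composite
score. Whether absence from a network should count as zero or as missing is
genuinely ambiguous, so both are reported: the appearance-weighted mean (the
default ranking key, with the appearance count alongside) and the
zero-filled mean. Ties break by descending prevalence, then identifier, so
reports are fully deterministic.

## The synthetic-data generator

`simulate_community()` emulates the study design the package targets: 64
samples in a balanced 2 (treatment) × 2 (cultivar) × 4 (growth stage)
factorial replicated across 4 field blocks. Counts come from a Gaussian
copula: a latent multivariate normal carrying the planted pairwise
correlations (identity elsewhere; a non-positive-semi-definite request is
rejected naming the offending pairs), plus a shared block-level offset
(`block_sd`, default 0.3) that couples all taxa within a block, mapped
through the standard normal CDF and inverted through a negative-binomial CDF
(default mean 50, dispersion 0.5 — heavily overdispersed, ~10% structural
zeros, as is typical of genus-level soil profiles). An independent Bernoulli
mask then thins presences so expected prevalence equals `prevalence_target`
(default 0.8, emulating the prevalent fraction of taxa that actually enters
network inference; a target of 1 disables the mask). The copula construction
is chosen precisely because rank correlation survives monotone marginal
transforms, matching the Spearman-based inference being tested.

Two consequences are worth stating. First, the planted rank structure lives
among *positive* counts: the independent mask replaces values with zeros at
random, which attenuates full-sample Spearman correlations — measurably, and
by design. Recovery experiments (planted-edge precision/recall, hub
prioritization) therefore run with the mask off, while a separate property
test measures that the planted signal survives on jointly-positive samples
under the default mask. Second, phenotypes are linear in `log1p` counts of
their planted taxa plus a block offset and Gaussian noise — a monotone,
smooth link that the lasso-on-abundances stage can represent.

What the generator does **not** emulate: compositional coupling from fixed
sequencing depth (each taxon's marginal is independent given the latent
field), taxon-specific abundance distributions, phylogenetic correlation,
and informative (abundance-dependent) zero inflation. Passing recovery tests
therefore demonstrate correctness of the inference chain under a known
truth, not robustness to compositional artifacts — methods such as
SparCC/SPIEC-EASI address that separately and are out of scope.

## Problem sizes and determinism

Test and acceptance runs use desk-scale data chosen to exercise every code
path while keeping the full suite fast: 30–64 taxa × 64 samples for
recovery experiments (20–100 seeds per rate), 1000 replicates × 199
permutations for PERMANOVA calibration, n = 1000 samples for power-law
exponent recovery, and complete enumeration (all label permutations, all
node partitions) only at n ≤ 9 where it is exact. Every stochastic stage
takes an explicit seed; the pipeline expands one global seed into per-stage
substreams recorded in its manifest, so reruns are hash-identical.

## Known limitations

* PERMANOVA is single-factor (with strata); interaction partitioning is not
  implemented.
* The Jaccard distance is binary; the abundance-weighted variant is not
  offered.
* Association p-values use the t approximation, which is anticonservative
  for very small n; an exact permutation option would be the natural
  extension.
* Walktrap is a heuristic: the max-modularity guarantee is verified
  exhaustively only on small graphs.
* The composite centrality weights the three normalized metrics equally;
  no data-driven weighting is attempted.
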