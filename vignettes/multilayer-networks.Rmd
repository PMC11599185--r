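---
title: "Multilayer signaling networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer signaling networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlsignet)
```

# Overview

`mlsignet` reconstructs intercellular-plus-intracellular signaling as a
four-layer directed network — ligands expressed by a *sender* cell
population (immune cells), receptors, transcription factors (TFs) and
target genes expressed by a *receiver* population (cancer cells) — and
compares the networks of two tumour-grade conditions. This vignette
documents the statistical model at each stage, the tunable parameters,
the synthetic-data generator that the test suite runs against, the
numerical choices, and the limitations a user should know about.

# Pipeline model, stage by stage

## Quality control

Cells are filtered before genes, in a fixed, logged order: first cells
whose mitochondrial + spike-in (ERCC) counts exceed 25% of their total
(`max_mito_ercc_fraction = 0.25`), then cells detecting fewer than 50
genes (`min_genes_per_cell = 50`), then genes detected (count > 0) in
fewer than 3 surviving cells (`min_cells_per_gene = 3`). Fixing the
order makes the filter deterministic; with these thresholds a second
application is a no-op on all data the generator produces, and the test
suite asserts that idempotence. Mitochondrial and spike-in genes are
recognized by the name prefixes `MT-` and `ERCC-` (both configurable
regexes in `expr_matrix()`).

## Normalization and dimensionality reduction

Counts are depth-normalized and log-transformed:
`normalized[g, c] = log(1 + 10000 * counts[g, c] / total[c])`, natural
logarithm, scale factor 10,000. This gives the exact per-cell identity
`sum_g expm1(normalized[g, c]) = 10000`, which the suite checks to
machine precision on every fixture.

Gene selection ranks genes by a variance-stabilized dispersion: the
variance of the normalized values divided by a loess trend of
log-variance on log-mean (span 0.5, degree 2). When fewer than 30
positive-mean genes are available, or the trend fit is degenerate, the
raw variance is used instead — small fixtures should not fail on a
smoother. The top 2,000 genes (or all genes, with a warning, when the
matrix is smaller) are z-scored per gene with values clipped at ±10 — a
conventional guard against a handful of extreme cells dominating the
PCA — and the first 20 principal components of the scaled matrix form
the cell embedding.

## Clustering and annotation

A k-nearest-neighbour graph (k = 20, Euclidean distance in PC space) is
re-weighted by the Jaccard similarity of neighbourhoods (shared nearest
neighbours, self included), pruned below 1/15, and clustered by Louvain
modularity optimization at resolution 0.5. Labels are renumbered 0-based
by decreasing cluster size, which makes the labelling invariant to cell
order. The resolution default is a convention, not a derived choice; a
sweep is possible by calling `cluster_cells()` repeatedly but no
model-selection rule is applied.

Markers are found per cluster by a one-vs-rest Wilcoxon rank-sum test on
the normalized layer, keeping positively enriched genes with
Benjamini–Hochberg adjustment. The implementation uses the exact
rank-sum null distribution on small tie-free samples and the
normal approximation with tie and continuity corrections otherwise —
the same dispatch rule as `stats::wilcox.test`, against which it is
tested.

Cluster annotation is automated: `score(cluster, type)` is the mean
normalized expression of the type's reference markers over the cluster's
cells, each cluster takes the argmax type, all-zero scores yield the
sentinel `"unknown"`, and ties break lexicographically with a warning.
In a real analysis this step is usually manual; automating it against an
explicit reference marker table is what makes the pipeline testable, and
the table plays exactly the role of the curated marker list a human
would use.

## Network construction

*Highly expressed* means detected in at least `he_fraction = 0.10` of
the cells of a type. The threshold is deliberately a parameter
(`mlnet_params()`): the filter is part of the method, the value is a
judgment call, and 10% is a conservative default for sparse scRNA-seq
counts.

Ligand–receptor edges are prior pairs whose ligand is highly expressed
in the sender type and receptor in the receiver type.

TF activation is tested by a one-sided Fisher exact test (equivalently a
hypergeometric upper tail): are the TF's annotated targets enriched
among the receiver's highly expressed genes, over the background of
genes detected in receiver cells intersected with the prior universe?
The background choice is explicit and testable. P-values are BH-adjusted
across TFs (raw-p mode is available for oracle comparison), retained at
adjusted p < 0.05. The Fisher test applies to TF activation and the
LASSO to TF→target selection; the receptor→TF layer is linked by prior
membership with both endpoints retained. The last choice is the weakest
link in the chain — no further pathway-significance statistic is
applied — and is flagged here deliberately: enriching it (e.g. with a
path-level test) would change only `link_receptor_tf()`.

TF→target edges: for each candidate target (a highly expressed receiver
gene annotated to at least one activated TF), its normalized expression
is regressed on the normalized expression of those activated TFs across
receiver cells with an L1 penalty. λ is chosen on a log grid by 10-fold
cross-validation under the 1-SE rule (`cv_1se`, the sparser and more
conservative choice; `cv_min` is available). The edge is kept iff the
fitted coefficient is nonzero *and* the pair is annotated. Multi-TF
designs go through `glmnet`; the single-predictor case uses the
closed-form soft-threshold solution with the same CV selection, since
`glmnet` requires two columns. Coefficients below 1e-10 in absolute
value are treated as exact zeros (full-shrinkage solutions are exact
zeros mathematically; floating point leaves ~1e-18 residue).

Assembly prunes every node and edge not on a complete
ligand→receptor→TF→target path. Because the graph is a layered DAG,
forward reachability from the ligand layer plus backward reachability
from the target layer computes the unique fixed point in one pass; the
suite verifies equality with a brute-force enumerate-all-4-paths oracle
on hundreds of random instances, and idempotence.

## Quadruples, grade specificity, enrichment

Quadruples are all (ligand, receptor, TF, target) 4-tuples whose three
consecutive edges exist, in lexicographic order; identity is the plain
4-tuple (edge statistics excluded), which is also how the two grades'
lists are intersected. Gene-set enrichment uses the union of all
quadruple genes as the query (per-quadruple enrichment at size 4 is
meaningless), a one-sided hypergeometric test per set, and BH across
sets — a generic stand-in for topology-aware pathway tools, which is a
documented divergence.

## Differential network and centralities

Edge and node set differences between grades use typed edges. All
centralities are computed on the directed graph — the network is
inherently directional; an undirected projection can be obtained via
`as_igraph()` if wanted for sensitivity analysis. Katz centrality
follows `x = (I − αAᵀ)⁻¹·1` (bias 1, attenuation α), solved directly;
the default α is `min(0.1, 0.85/spectral radius)`, and a layered DAG is
nilpotent so any α converges. PageRank uses damping 0.85, betweenness
directed shortest paths with (n−1)(n−2) normalization. Welch t-tests
compare per-node centralities between grades, BH-adjusted across the
three metrics tested (Katz, PageRank, betweenness). Zero variance in
both samples is reported as undefined rather than forced.

## Classification harness

Grade IV is the positive (minority) class. The protocol per iteration:
stratified 5-fold split with a derived, logged seed; within each fold
SMOTE (synthetic minority points interpolated uniformly between a
minority point and one of its 5 nearest minority neighbours) balances
the *training* data only; each model's small published grid
(`default_grids()`) is searched exhaustively by inner 3-fold accuracy;
the winner predicts the untouched test fold. A stratified 20% validation
split is carved out before any cross-validation and scored once per
model. The report retains fold assignments so leakage-freedom is a
structural assertion, not a hope: fold membership is identical with
SMOTE on or off, test folds and the validation set never contain
synthetic points, and metrics (accuracy, precision, recall, F1; percent
scale) are cross-checked against hand-computed confusion matrices.
The full protocol is 100 iterations; scaled-down runs simply set
`n_iterations` lower.

One behavior worth understanding: with SMOTE-balanced training, a model
fit on label-permuted data predicts both classes at roughly equal rates,
so its null accuracy sits between 50% and the majority rate. The
"null accuracy ≈ majority rate" sanity check therefore runs with
`smote = FALSE`.

## Prognosis

The risk score is the linear combination `sum_g beta_g * expression_g`,
no intercept, with β from a multivariate Cox proportional-hazards fit
with the Efron tie approximation (equal to Breslow on tie-free data, as
the suite checks). A univariate screen is available and reported but
non-blocking: the final model fits the stated gene list directly.
Kaplan–Meier strata split at the median score by default (the cutoff is
configurable); significance is the standard log-rank test.
Time-dependent AUC uses the cumulative-case / dynamic-control
formulation with inverse-probability-of-censoring weights from the
Kaplan–Meier estimate of the censoring distribution; without censoring
it reduces exactly to the binary AUC of "event by horizon" against the
score, and the suite asserts that equivalence. Years convert at 365.25
days. Train/test splitting for evaluation defaults to 70% with split
ratios configurable between 60 and 90%.

# The synthetic-data generator

The generator is first-class, tested code: it defines the conditions
under which every downstream claim is verified.

**Prior database.** Role-prefixed gene names (`LG_`, `RC_`, `TF_`,
`TG_`); each relation table is Bernoulli-sampled at `edge_density =
0.02`. Curated ligand–receptor resources hold a couple of thousand pairs
over hundreds of ligands and receptors (density well under 1%), and
TF–target annotations are similarly sparse; 0.02 is realistic while
keeping small simulated databases connected. Every TF is guaranteed at
least one annotated target (a target-less TF would be an invalid entry,
so the generator repairs rather than returns it).

**Planted cascades.** `plant_cascades()` selects disjoint
(ligand, receptor, TF) axes — 10 by default, the last 3 tagged
grade-IV-only — and attaches 8 activity-coupled targets per TF,
inserting any missing chain edges into the prior. An active TF drives a
regulon, not a single gene; several coupled targets are also what makes
the Fisher activation stage identifiable at all (a one-target TF can
never be significantly enriched).

**Expression.** Counts are gamma-Poisson (negative binomial) with
dispersion 0.3; `noise_dispersion = 0` is implemented as the exact
deterministic limit (counts = rounded means) so noiseless
identifiability tests are literal. Inactive genes have mean 0.05
(≈ 5% detection, below the 10% highly-expressed threshold); active
cascade genes are boosted ×20 (≈ 60% detection, safely above it).
Each receiver cell carries a latent per-cascade TF activity
η ~ N(0, 1) on the log-mean scale; the TF's log-mean is shifted by η
and each coupled target's by `slope · η` with slopes drawn from
U(0.7, 1.5) — heterogeneous regulon strengths. These defaults were fixed
at design time so that the planted structure is identifiable under the
conservative 1-SE LASSO rule while staying in a realistic
sparse-counts regime, and they define the study conditions for the
acceptance checks. Grade-IV-only cascades simply receive no boost in
the grade-III condition, so both grades share one gene universe.
Housekeeping (`HK_`, mean 3), marker (`MK_<type>_k`, mean 2 in their own
type), mitochondrial and spike-in genes give cells realistic library
composition; a stated fraction of cells (5% by default) has
mito/ERCC means inflated ×60 so they unambiguously fail the 25% QC rule,
and their ids are recorded as planted QC failures.

**Survival cohort.** Standardized normal expression for the model genes;
event times exponential with rate `baseline_hazard · exp(Σ βg xg)`, so
the planted score is the true log relative hazard; independent
exponential censoring with its rate calibrated by root-finding so the
expected censored fraction matches the request. The default planted
coefficients are the four-gene vector the prognostic model is expected
to recover. A companion two-grade bulk cohort (520 vs 172 patients,
mean shifts of roughly one standard deviation on the four genes)
provides the imbalanced classification setting.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: batch effects and their correction,
doublets, ambient RNA, UMI saturation, cell-cycle or other latent
covariates, autocrine signaling, pathway intermediates between receptor
and TF, spatial structure, and any real database's biases. Tests verify
the statistical machinery, not biological discovery.

# Problem sizes and determinism

The test and acceptance runs use: 800 cells per grade (500 receiver,
200 sender, 100 bystander) over ≈ 450 genes; a one-off study-scale QC
fixture of 6,341 cells with exactly 100 planted failures (expected
retention 6,241); 20 independent n = 500 survival cohorts for
coefficient recovery plus 100 for log-rank power; 4,000 replicates per
null-calibration check; on the order of a thousand randomized
brute-force oracle instances (≤ 12–20 nodes); and a 10-iteration run of
the 100×5-fold classification protocol on the 692-patient cohort. These
sizes keep the full suite around a minute or two on one CPU while
leaving the Monte-Carlo margins comfortable, and are the package's
choices of scale, stated here so they can be grown.

All randomness flows through a single user seed via a hash-derived
child-seed scheme (`derive_seed`), so every generator call and every
cross-validation split is reproducible and independently re-derivable.

# Known limitations

- The receptor→TF link is prior membership only; no path-level
  significance is computed.
- Enrichment is a plain hypergeometric over gene sets, not a
  topology-aware pathway analysis.
- The Cox coefficient-recovery tolerance (±0.15 at n = 500 with two
  near-zero planted coefficients) is close to two standard errors, so
  any *single* cohort recovers all four signs with probability ≈ 0.8;
  the acceptance suite therefore checks aggregate recovery across
  cohorts alongside the per-cohort rate.
- SMOTE interpolates in feature space and is appropriate for the
  low-dimensional quadruple features; for high-dimensional expression
  it would need a different distance.
- Louvain is stochastic; results are seed-pinned, and label *sets* (not
  indices) should be compared across runs.
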