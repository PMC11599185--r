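# mlsignet

Multilayer ligand–receptor–TF–target signaling networks from single-cell
expression data, with grade-differential network analysis, cascade-based
classification, and survival modelling.

## The problem

Tumor progression is driven in part by how malignant cells talk to their
microenvironment. In high-grade glioma, immune cells secrete ligands that
bind receptors on cancer cells; receptor engagement activates
transcription factors (TFs) in the receiving cell, which in turn regulate
target genes. `mlsignet` reconstructs this chain as a four-layer directed
network

```
ligand  →  receptor  →  TF  →  target
(sender)   (receiver)  (receiver)  (receiver)
```

from single-cell RNA-seq counts plus prior-knowledge relation tables
(ligand–receptor pairs, receptor–TF links, TF–target annotations), builds
one network per tumour grade, and asks which complete signaling cascades
("quadruples", e.g. *PDGFA–PDGFRA–CREB1–PLAT* in glioma) distinguish the
grades, classify patients, and predict survival.

The package is aimed at computational biologists who want a tested,
fully synthetic-data-exercisable implementation of this kind of pipeline:
every stage can be run against generated data with planted ground truth,
so each statistical step is verifiable end to end.

## The model at each stage

| Stage | Method |
|---|---|
| QC | drop cells with mito+ERCC count fraction > 25% or < 50 detected genes; drop genes detected in < 3 cells |
| Normalization | `log(1 + 10,000 · count / cell total)` (natural log) |
| Feature selection | top 2,000 variance-stabilized dispersion genes; z-score (clipped ±10); 20 PCs |
| Clustering | shared-nearest-neighbour graph (k = 20, Jaccard weights), Louvain modularity at resolution 0.5 |
| Annotation | argmax of mean marker expression per cluster against a reference marker table |
| L→R edges | prior pairs with ligand highly expressed (detected in ≥ 10% of cells) in senders, receptor in receivers |
| TF activation | one-sided Fisher exact test: enrichment of the TF's annotated targets among highly expressed receiver genes, BH-adjusted, α = 0.05 |
| TF→target edges | per-target LASSO of target expression on its activated TFs across receiver cells; λ by 10-fold CV (1-SE rule); edge kept iff coefficient ≠ 0 and pair annotated |
| Assembly | prune every node/edge not on a complete L→R→TF→target path |
| Differential analysis | edge/node set differences; degree, Katz `x = (I − αAᵀ)⁻¹1`, PageRank, betweenness; Welch t-tests, BH across the three metrics |
| Classification | quadruple-gene features, SMOTE balancing (training folds only), repeated stratified 5-fold CV with inner grid search: decision tree, random forest, k-NN, SVM, logistic regression, XGBoost |
| Prognosis | risk score = Σ βg·expressiong from a multivariate Cox fit (Efron ties); Kaplan–Meier median split + log-rank; IPCW time-dependent AUC at 1/3/5 years |

## Worked example

```r
library(mlsignet)

# synthetic two-grade study: 10 planted cascades (3 grade-IV-only),
# 500 receiver cells per grade, with full ground truth
sim <- simulate_study(seed = 42)

ex  <- apply_qc(sim$grade_IV)
ex  <- normalize_cells(ex)
ex  <- select_hvg_scale_pca(ex)
cl  <- cluster_cells(ex, seed = 42)
ann <- annotate_clusters(ex, cl, sim$truth$reference_markers)

net <- mlnet(ann$expr, sim$prior, grade = "IV", seed = 42)
net
#> Multilayer signaling network (grade IV): immune -> cancer
#>   layers: 10 ligands, 10 receptors, 10 TFs, 68 targets
#>   edges: 94 (LR 14, RTF 12, TFT 68)

head(enumerate_quadruples(net), 3)
#>   ligand receptor     tf target
#> 1 LG_013   RC_002 TF_040 TG_002
#> 2 LG_013   RC_002 TF_040 TG_023
#> 3 LG_013   RC_002 TF_040 TG_089
```

All 10 planted cascade axes survive as the network's 10 ligands,
receptors and TFs; the 94 edges are the prior relations whose endpoints
passed the expression, activation and LASSO filters.

Survival modelling over a cohort whose hazard follows a planted linear
score:

```r
pb <- c(LG = -0.06759852, RC = 0.08573037, TF = -0.84328532, TG = 0.82401982)
cohort <- generate_survival_cohort(500, betas = pb, censoring_rate = 0.2,
                                   seed = 42)
model <- multivariate_cox(cohort, names(pb))
model
#> Cox risk-score model: risk = sum(beta_g * expression_g)
#>   LG       beta = -0.126085  (HR 0.882)
#>   RC       beta = +0.090296  (HR 1.094)
#>   TF       beta = -0.873215  (HR 0.418)
#>   TG       beta = +0.821020  (HR 2.273)

km <- km_stratify(cohort, risk_score(model, cohort))
#> log-rank chi-square = 195.5, p = 2.01e-44
```

The fitted coefficients recover the planted values (−0.068, 0.086,
−0.843, 0.824) to within sampling error, and the median risk-score split
separates the two survival strata decisively.

## Vignette

`vignettes/multilayer-networks.Rmd` documents the model assumptions, the
synthetic-data generator's design (what it emulates and what it leaves
out), every tunable parameter with its default and rationale, numerical
choices, and known limitations.
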