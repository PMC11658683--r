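---
title: "Sertoli and granulosa cell-identity scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sertoli and granulosa cell-identity scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gonadscore` implements a pipeline for single-cell RNA-seq of the fetal
mouse gonad that asks, for every cell, how far it has progressed towards a
Sertoli (testicular supporting) or granulosa (ovarian supporting) fate. The
two outputs — the Sertoli cell identity (SCI) and granulosa cell identity
(GCI) scores, each on a 0–100 scale — come from a pair of logistic models
over small gene signatures selected by cross-validated stepwise search over
an ROC-AUC-ranked gene list. On top of the scores sit a rectangular-
hyperbola classifier for "double-positive" cells co-expressing both
programs, an ICA projection with logistic label transfer for comparing
datasets from different mouse strains, and the proportion/score statistics
used to contrast genotypes (XX wild type, XY wild type, and XY Znrf3-null,
which shows partial gonadal sex reversal).

Everything runs against a synthetic-data generator with planted ground
truth, so each stage can be checked quantitatively without any external
download.

# The synthetic-data generator

`simulate_dataset()` draws sparse gene-by-cell counts from a negative
binomial with per-gene mean `nb_mean` and dispersion `alpha =
nb_dispersion`, i.e. variance `mu + alpha * mu^2` — the standard
overdispersed model for UMI counts. Structure is added in four layers:

* **Cell types and markers.** Ten supporting-lineage-and-friends types
  (pre-supporting PS1/PS2, cycling pre-supporting, pre-Sertoli, Sertoli,
  granulosa, supporting-like cells, gonad progenitors, Leydig, germ). Each
  type owns a disjoint set of planted marker genes whose mean is multiplied
  by `exp(effect)` in cells of that type. The default is 50 markers per
  type at 1.5 natural-log units (~4.5-fold) — the order of magnitude of
  canonical markers such as *Sox9*/*Amh* in Sertoli cells or *Foxl2*/*Fst*
  in granulosa cells — among 2,000 genes, with 200 cells per type.
* **Composition.** Each sample is one (genotype, stage, replicate); its
  cells' types are multinomial draws from a mixture table. The default
  table encodes the broad developmental shifts: progenitors dominate at
  11.5 dpc, Sertoli cells expand in XY and granulosa cells in XX gonads by
  14.5 dpc, and XY Znrf3-null gonads acquire granulosa cells at the expense
  of Sertoli cells. The proportions are design choices (the per-sample
  composition of the real data is not published), so tests that need exact
  per-type cell counts use `uniform_mixture()` instead.
* **Double-positive cells.** A fraction `dp_fraction` (default 0.1) of
  Sertoli and granulosa cells is drawn as a latent intermediate class
  expressing *both* programs at `dp_attenuation = 0.7` of the full effect.
  This mimics cells co-expressing pro-Sertoli and pro-granulosa markers
  without asserting any mechanism; the truth table records them as `DP`
  while their observable label stays the assigned cluster type.
* **Nuisance structure.** Per-cell library size is log-normal (`sigma =
  0.3`) so percentile QC filters have genuine outliers to remove, and 13
  `mt-` genes absorb a per-cell mitochondrial fraction drawn from
  `mito_fraction_range` (default 2–10%).

The generator does **not** simulate doublets, ambient RNA, batch effects or
spliced/unspliced layers. Passing tests therefore demonstrate correctness
of the algorithms under a clean negative-binomial world, not robustness to
every artefact of real droplet data.

# Quality control and normalisation

`filter_cells()` applies, per sample, percentile band filters on total
counts (2nd–98th), genes expressed (2nd–98th) and percent mitochondrial
RNA (2nd–95th), then a global filter removing cells in the bottom 5th
percentile of counts over the retained cells. Numerical conventions, since
these change which cells survive:

* percentiles are linear-interpolation quantiles (R type 7), and the same
  convention is used everywhere a percentile appears (QC, the DP boundary);
* removal is strict (`< low` or `> high`), so a degenerate sample in which
  all cells are identical loses nothing;
* samples with fewer than 10 cells skip the per-sample filters with a
  warning — percentiles of a handful of cells are noise;
* the often-quoted "~5,000 counts" style cutoff is a *consequence* of the
  percentile rule on a given dataset, not a fixed threshold; only the
  percentile rule is implemented.

`normalize_counts()` scales each cell to a target sum of 10,000 counts and
applies `log1p`. The size factor is computed from counts of genes outside
the top 5% most highly expressed (by total count), so a few dominant genes
cannot compress everything else; excluded genes are still scaled and
logged, they are only left out of the size-factor sum. Cells whose
non-excluded sum is zero fall back to their total sum with a warning.

`assign_cell_cycle()` uses the standard module-score construction: genes
are binned by average expression (25 bins), each signature gene contributes
up to 100 control genes from its own bin, and the score is mean signature
expression minus mean control expression. Phase is S if the S score is
positive and exceeds the G2/M score, G2M if the G2/M score is positive and
at least the S score, else G1 — so the three phases always partition the
cells. The control draw is seeded and, like the original, run per sample.

# Gene ranking and the identity models

**Ranking.** For a target type within a scope (granulosa vs the rest of
the XX sample; Sertoli vs the rest of the XY samples), every expressed gene
(≥3 scoped cells by default) is scored by the ROC AUC of its expression as
a single-gene classifier. `compute_auc()` is the exact Mann–Whitney form —
rank sums with midranks, so ties get half credit. `rank_genes()` offers the
single-gene binomial GLM route (`method = "glm"`): the AUC of the fitted
probabilities. Because the logistic link is monotone, that AUC equals the
raw-expression AUC (or its complement when the slope is negative), so
`method = "rank"` computes the same ranking directly and is the faster
equivalent; a test asserts per-gene equality to 1e-12. Genes are ranked by
|AUC − 0.5| so strong negative markers rank high too, with the sign kept as
a `direction` column.

**Stepwise selection.** `build_identity_model()` walks the ranking in
order. A candidate gene joins the logistic model only if the mean held-out
ROC AUC over stratified 5-fold cross-validation improves on the running
best (empty model = 0.5) by more than `tol = 1e-4`. Selection stops at 50
accepted genes — the signature-size cap, kept for consistency between the
two models — when the ranking is exhausted, or after 20 consecutive
rejections (`patience`). Folds are drawn once, seeded, and reused for every
candidate so that comparisons across candidates are not confounded by fold
noise. CV AUC is evaluated on held-out folds only. The final model is
refitted on all scoped cells. With `tol = Inf` nothing can be accepted and
the function refuses to return an empty model. Note the selection is
deliberately greedy and slightly noisy — with many weakly informative genes
CV noise lets the model keep growing to the cap, which is the intended
behaviour of a stepwise-AIC-style rule.

**Scoring.** `score_cells()` returns `100 * plogis(intercept + coef ·
expression)` per model. The 0–100 probability scale is a design choice (it
matches the magnitudes these scores are usually reported on); a cell with
zero expression of every signature gene scores exactly
`100 * plogis(intercept)`. All cells are scored, including genotypes not
seen in training; signature genes missing from a matrix are imputed as zero
with a warning.

# Double-positive cells

With `a = 10` fixed and `b` the 97.5th percentile of GCI among reference
cells — wild-type XX granulosa cells at 14.5 dpc, requiring at least 20
such cells — a cell is double positive iff `sci * gci >= a * b`. The exact
algebraic form of the original hyperbola is not recoverable from the text
it was described in, so the rectangular hyperbola was chosen: it honours
every stated property (`a` scales, `b` bounds, the axes are asymptotes so a
cell scoring 0 on either identity is never flagged, and jointly elevated,
similar scores are). The predicate is isolated in `is_double_positive()` so
an alternative functional form is a one-line swap; boundary equality counts
as inside. Do not expect this surrogate to reproduce any particular
published DP count.

`dp_proportions()` tabulates DP rates per genotype × stage × cell type and
compares genotypes pairwise with a 2×2 chi-square on (DP, non-DP) counts,
switching to Fisher's exact test (flagged) when any expected count is
below 5, with Benjamini–Hochberg correction across all comparisons.

# Cross-strain projection and label transfer

`fit_ica()` centres the cells × genes matrix on the per-gene mean, whitens
to `k` components via SVD, and runs symmetric fixed-point ICA with the
logcosh contrast (seeded random rotation start, symmetric decorrelation
each step). The stored centre, whitening matrix and orthogonal rotation
define the projection `scores = R K (x − centre)` used by `project_ica()`
— the standard whiten-then-rotate pipeline; any transposition is layout
bookkeeping. Projection aligns genes by identifier, imputes missing model
genes as zero (warning), and refuses to project when fewer than half the
model genes are present. Projecting the training data reproduces the
training scores exactly, and projecting the centre gives the origin. `k`
defaults to 30 and is configurable; the fixed-point iteration can stall on
real-ish data (tolerance 1e-4, 200 iterations), in which case the current
rotation is returned with a warning — the projection is unaffected since
any returned rotation is orthogonal.

`transfer_labels()` trains multinomial logistic regression (via `nnet`) on
up to 500 randomly subsampled cells per class — sampling without
replacement, classes smaller than the quota use all cells with a warning —
and predicts per-query-cell class probabilities (rows sum to 1) and argmax
labels. Batch-balanced neighbour graphs and UMAP embeddings are out of
scope; the module ends at component scores and transferred labels.

# Proportion and score statistics

`cell_type_proportions()` computes per-sample composition over included
types (blood/immune/mesothelial/endothelial-style clusters are the
intended exclusions). `compare_proportions()` pools counts across samples
within genotype before testing each cell type's 2×2 (in-type vs out-of-
type) table — pooled chi-square without Yates continuity correction by
default, both configurable, Fisher fallback as above. Whether testing
should be pooled or per sample is genuinely open; pooling is the default
because the published comparisons are per genotype, and per-sample tables
are available from the same proportion table. `pca_proportions()` is a
centred, unscaled PCA of the sample × type proportion matrix.
`compare_scores()` runs two-sided unpaired Wilcoxon rank-sum tests (exact
when both groups have ≤25 observations and no ties; normal approximation
with continuity correction otherwise), BH-corrected.

One caution surfaced by testing: chi-square and Fisher p-values on the same
2×2 table agree closely only for large counts. With every cell ≥100 the
absolute difference can still reach ~0.03; agreement within 0.005 is only
reliable once counts reach the thousands. The package exposes both routes
and flags which one was used.

# Problem sizes and reproducibility

The test suite exercises the full pipeline at the generator's reference
conditions (200 cells/type, 50 markers/type at 1.5 ln-units among 2,000
genes — about 2,000 cells) and smaller variants for unit tests; the whole
suite runs in well under a minute on one core. Every stochastic step
(generation, fold assignment, control-gene draws, ICA initialisation,
subsampling) takes an explicit integer seed, and `scripts/acceptance.R`
derives all of its seeds from a single `--seed` argument, so runs are
bit-reproducible.

# Known limitations

* The DP hyperbola is a surrogate form (see above).
* The stepwise search is greedy with a patience heuristic; it makes no
  claim of finding the optimal gene subset, only a well-discriminating one
  of bounded size.
* The simulator's clean negative-binomial world contains no doublets,
  ambient contamination or batch structure, so pipeline performance there
  is an upper bound on real-data behaviour.
* Scores are calibrated logistic probabilities *under the training scope*;
  applying a model across strains or datasets is supported but the
  probability scale then inherits any covariate shift.
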