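---
title: "Methods: cross-dataset comparison of blastoid models and blastocysts"
author: "blastoidCompare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset comparison of blastoid models and blastocysts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each statistic assumes, which tunable parameters
matter, what the synthetic-data generator does and does not emulate, and
where the design was genuinely open.

## The comparison problem

Blastoids from different founding cell lines are sequenced by different
labs on different platforms (droplet UMI counts versus plate-based TPM),
at different depths and sizes. Three questions structure the analysis:
how do cell-type compositions differ across models; how similar are the
transcriptomic identities of matched cell types; and how do datasets
distribute over a joint transcriptomic landscape. Each question gets a
statistic whose assumptions tolerate cross-platform data: counts enter
only through within-dataset normalization; cross-dataset comparisons are
made on proportions, ranks, or per-dataset standardized scores.

## Quality control

Genes detected in fewer than 10 cells and cells with fewer than 100
detected genes are removed (strict "fewer than": a gene in exactly 10
cells survives). Cells with mitochondrial fraction strictly above 20% are
removed. For UMI data only, cells outside density-inflection thresholds on
total counts are removed; TPM cells all sum to ~1e6, so a count filter
would be vacuous there and is recorded as skipped.

The inflection threshold estimates a Gaussian-kernel density (Silverman's
bandwidth) of `log10(counts + 1)` and takes the minimum between the main
mode and a secondary mode on the flagged side. Two guards matter in
practice: a mode must reach at least 5% of the peak density, and the
valley between modes must drop below half the smaller peak — without
them, KDE wiggles on a perfectly unimodal sample masquerade as a second
population and the "threshold" lands mid-distribution. When no qualifying
second mode exists the threshold falls back to a quantile (0.01 lower,
0.99 upper). The quantile fallback trims a further tail sliver on every
re-application, so repeated filtering reuses the first pass's thresholds
(`count_thresholds=`), under which the filter reaches a fixed point; only
the gene-detection filter may cascade. Filters are applied gene-rule
first, then cell rules, in one pass by default.

## Normalization, variable genes, covariates

UMI values are pseudo-log normalized, `ln(1 + count * 1e4 / cell_total)`;
TPM values as `ln(1 + tpm)`. Variable genes are ranked by the residual of
`log(variance)` from a degree-2 polynomial trend on `log(mean)` — a
deliberately plain stand-in for variance-stabilizing selection; faithful
reproduction of any specific published implementation is a non-goal.
Technical covariates (spike-in fraction, feature and count totals,
cell-cycle scores, all user-supplied) are removed by per-gene OLS;
residuals are z-scored and clipped at ±10 to bound outlier influence. A
residual standard deviation at numerical-noise scale relative to the gene's
own scale is treated as an exact fit and zeroed rather than rescaled.

## Lineage module scores

A module score contrasts a marker set against expression-matched
controls: genes are placed into 25 equal-frequency bins by across-cell
mean expression (ties broken by gene index, for determinism); each set
gene contributes 100 control genes sampled from its bin (without
replacement when the bin suffices); the cell's score is the set's mean
expression minus the mean over all sampled controls. Bin and control
counts follow the cited method's common implementation — the source
method leaves them unstated — and both are exposed. The construction
makes scores invariant to per-cell additive shifts, and the seeded draw
makes them bitwise reproducible.

Three variants serve different views: raw scores; min-max to [0, 1]
across the full integrated cell set (one shared landscape, so one shared
scale; a constant score maps to zero); and per-dataset z-scaling — each
score centered and scaled within each dataset — which is the variant the
KS comparison consumes, because it removes dataset-level location/scale
(batch) differences while preserving distribution shape.

## Consensus annotation

Three annotators are deliberately simple re-specifications of the tool
classes used in practice (cluster-level marker scoring, high-specificity
per-cell scoring, reference projection); the consensus design is the
point, and fidelity to any one published tool is a non-goal.

1. *Cluster-level*: per-gene z-scores, summed over a cluster's cells and
   a lineage's markers with specificity weights `1/sqrt(#lineages listing
   the gene)`; argmax labels the cluster, and a cluster whose top score is
   below a quarter of its size — the cited cluster method's convention —
   is `unknown`. Clusters under 3 cells are `unknown`.
2. *Per-cell margin rule*: lineage score is the mean marker z-score; a
   cell is labeled only when the top score is positive and beats the
   runner-up by 0.25.
3. *Reference centroids*: per-label mean profiles on the genes that best
   separate the reference labels (top between-centroid variance, 10 per
   label, at least 30 — correlating over all genes lets shared background
   expression swamp the label signal, which is why a small discriminating
   signature is used); Spearman correlation per query cell; `unknown`
   when top-minus-median correlation is under 0.05.

The consensus is a per-cell majority vote with `unknown` counting as a
label; a three-way disagreement yields `unknown` — no majority exists,
and conservative assignment matches the high unknown fractions such
surveys report. PE cells are optionally split into subtypes I/II by
membership in a user-supplied list of landscape clusters (the subtype-II
signature rides with amnion markers in both the marker panel and the
generator).

Rank-sum markers between groups use the two-sided Wilcoxon test (normal
approximation with tie correction), `ln((mean(expm1(x))+1))` fold changes
(the standard convention for log1p-normalized data), BH adjustment within
each group, and exclusion of mitochondrial (`MT-`) and ribosomal
(`RPS`/`RPL`) genes.

## Composition analysis

Contingency tables are sources × cell types — pooling datasets of the
same founding line — with PE subtypes pooled for the primary test; this
is what yields df = 6 for 4 sources × 3 types and df = 9 with the
unknown column, and the plain Pearson χ² (no Yates correction) is the
form those statistics imply. Expected-count zeros (an empty source or
type) are an error instructing removal rather than a silent drop.
Composition clustering is average-linkage on row-normalized proportions.

## Joint landscape and distribution distances

The landscape is a baseline shared-gene PCA: variable genes are ranked
per dataset, combined by cross-dataset median rank (top 2,000 shared),
z-scaled per dataset, concatenated, and projected to 10–15 components.
Published integration methods (reciprocal PCA, CCA, MNN, Harmony) are
out of scope by design — all downstream distribution statistics accept
an externally supplied cluster assignment file, so integrated clusters
can be plugged in. PCA is computed from the gene-gene cross-product
(genes ≪ cells) and component signs are fixed by the largest-loading
convention, making the embedding deterministic. Clustering is a
Jaccard-weighted shared-nearest-neighbor graph (k = 20) with seeded
Louvain at resolution 2.0 — high enough to resolve scarce cell types in
small datasets; cluster ids are relabeled by decreasing size.

Per-dataset cluster proportions are compared two ways. Jensen–Shannon
divergence uses all clusters, natural logs and `0·log 0 := 0`, matching
the referenced implementation's default unit (whether that tool used
divergence or its square root, and which log base, is not stated
anywhere authoritative; the metric variant — square root of the base-2
divergence, which satisfies the triangle inequality — is available and
the default documented). Pearson correlation distance
`(1 − cor)/2` is computed on the support intersection — clusters with
strictly positive proportion in both datasets, the adopted reading of
"shared between a pair" — and a pair with fewer than 3 shared clusters
or zero variance is masked as undefined rather than fabricated, since
correlation on ≤ 2 points is degenerate. Heatmap ordering uses
average-linkage clustering, imputing masked entries with the maximum
defined distance (with a warning).

## Bootstrapped KS distances

For one module, each dataset contributes its z-scaled score distribution.
Per iteration, every dataset is subsampled with replacement at the
smallest dataset's cell count (the size is always derived from the data
at hand and recorded, never hard-coded); the exact two-sample KS
statistic is evaluated over the pooled sorted values; the reported matrix
is the element-wise mean over 1,000 iterations. Sampling with replacement
is used uniformly — the sensitivity procedure states it explicitly and
consistency favors one scheme. Within an iteration, one draw per dataset
is reused against all partners, which makes the matrix exactly symmetric
(independent draws per pair would break symmetry for no statistical
gain); the diagonal is a second, independent self-draw and is reported
rather than zeroed, because the self-resampling distance is the natural
`O(n^{-1/2})` null scale for reading the off-diagonal entries.

The sensitivity analysis repeats the computation at sizes 100, 400, 800,
1000, 1500 and reports element-wise differences to the reference-size
matrix, Frobenius norms, and Spearman rank correlations of off-diagonal
distances — absolute distances drift with subsample size, so conclusions
should rest on the rankings, which is what the rank correlations certify.

## Pathway activity

Per cell, genes are ranked by decreasing expression — ties (dominated by
zeros) broken by a single seeded random permutation, avoiding systematic
gene-order bias while staying reproducible — and the recovery AUC of a
gene set within the top 5% of ranks is `sum_k hits(k)` normalized by
`sum_k min(k, |S|)`, so perfect top-ranking scores exactly 1. The top
fraction and tie seed follow the cited tool's defaults since none are
stated. The score depends on ranks only, hence is invariant to monotone
transforms of expression. Gene-set membership (GO exports, GMT format) is
user-supplied, not bundled: membership is annotation-version-dependent.
Aggregation by cell type / cluster / dataset emits empty combinations as
missing, never zero.

## The synthetic cohort generator

The generator emulates what the statistics assume: several datasets of
unequal size and platform; lineage programs (EPI_ICM, PE-I, PE-II with
amnion markers attached, TE) planted as `exp(2)`-fold marker inflation by
default; three composition archetypes — balanced (TE-majority,
blastocyst-like), EPI-enriched, PE-enriched — with 5% EPI–TE
intermediate cells whose expression is a convex program mixture with
weight uniform on (0, 1); per-cell Beta mitochondrial fractions (mean
0.05, concentration 50), optionally materialized into an inflated `MT-`
gene block so the QC path is exercised end to end; log-normal library
sizes around 8,000 UMIs; negative-binomial counts at gene dispersion 0.3
(the standard overdispersed scRNA-seq model); TPM as log-normal noise on
the program rescaled to 1e6 per cell; a per-dataset log-normal gene shift
(sd 0.1) as a mild batch effect; optional Bernoulli dropout, default 0
since negative-binomial counts are already zero-rich. One cohort seed
spawns per-dataset sub-seeds (`seed + index`), giving byte-identical
regeneration with dataset-level independence.

What it does **not** emulate — ambient RNA, doublets, read-level noise,
or gene–gene correlation beyond the lineage programs — bounds what
passing tests show: they certify the statistics and their contracts on
data satisfying the model's assumptions, not robustness to every artifact
of real droplet data.

## Problem sizes and numerical choices

Tests and the acceptance script run at deliberately moderate sizes chosen
as the smallest that exhibit each property clearly: the archetype-recovery
cohort uses 9 datasets of 1,000–1,500 cells and 1,500 genes; KS
sensitivity uses 6 datasets × 500 cells with 150 bootstrap iterations
(the defaults remain 1,000); annotation recovery uses 500-cell reference
and query datasets over five seeds. Fixtures with few genes use
proportionally smaller embedding gene budgets. Other numerics: TPM cell
sums are validated to 1e-3 relative; distribution rows must sum to 1
within 1e-6; per-dataset z-scaling of a zero-variance module yields zeros
with a warning; min-max of a constant vector yields zeros; PCA signs are
fixed by largest loading; equal-frequency bin ties break by gene index.

## Known limitations

The baseline landscape does not correct batch effects, so its absolute
cluster structure is conservative relative to integrated landscapes —
cross-dataset statistics should be read through the distribution
distances, which are integration-agnostic, or computed on imported
integrated clusters. The three annotators share the same marker panel, so
the consensus vote is not fully independent evidence. Published
composition counts (supplementary workbooks) are treated as optional
external input, not bundled data, so the printed χ² statistics of the
motivating comparison are only reproduced when that file is supplied.
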