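---
title: "Design of the deconvolution benchmark: samplers, solvers and scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design of the deconvolution benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixbench)
```

`admixbench` evaluates bulk-transcriptome cell-type deconvolution under
controlled conditions: purified profiles with planted structure, admixtures
with exactly known proportions, and a fixed battery of scoring statistics.
This vignette explains the models behind each stage, the parameters that
matter, the numerical choices, and what passing the package's tests does
and does not establish about real data.

## The cell-type panel

The fine-grained panel holds 14 immune and stromal populations — memory and
naive B cells; memory, naive and regulatory CD4+ T cells; memory and naive
CD8+ T cells; NK cells; neutrophils; monocytes; macrophages; myeloid
dendritic cells; endothelial cells; fibroblasts — which aggregate into 8
coarse populations (B, CD4+ T, CD8+ T, NK, neutrophils, monocytic lineage,
endothelial, fibroblasts). Two cancer backbones (breast and colorectal cell
line stand-ins) complete admixtures but are never scored: deconvolution
targets the microenvironment, and admixed cancer cells act as structured
contamination. The in silico mixing panel excludes memory B cells, for which
no purified material is modelled; coarse ground truth is always derived from
fine ground truth by summation, so the two granularities are consistent by
construction.

## Synthetic purified profiles

The generator (`generate_profiles`) is deliberately simple and closed-form
testable:

* baseline gene means are log-normal (meanlog `log(50)`, sdlog 1.2), shared
  across cell types — heavy-tailed like real TPM but with no claim to match
  any real dataset's distribution;
* each type receives `markers_per_type` (default 20) disjoint marker genes
  whose expected linear expression is multiplied by `marker_fold_change`
  (default 8) in that type only;
* each replicate draws multiplicative gamma noise with coefficient of
  variation `baseline_dispersion` (default 0.15, a mid-range biological CV
  for purified bulk replicates);
* each of two vendor-like batches applies a per-gene log-normal factor with
  log-sd `batch_effect_sd` (default 0.1), mirroring a two-vendor sourcing
  design;
* counts are the noisy relative profile scaled to a library size drawn
  uniformly from `library_size_range` (default 0.8–1.2 million reads) and
  rounded; TPM is *defined* as counts per column scaled to 1e6, so the
  count/TPM consistency identity is exact.

Defaults were chosen once for realism and kept fixed. With fold change 8 and
default noise, every purified sample is classified correctly by a
mean-marker-expression oracle, and the measured own/other marker ratio sits
in [6, 10] after TPM renormalization (the markers themselves inflate their
own column total by roughly 10%).

The single-cell fixture (`generate_single_cell`) reuses the same expectation
profiles with per-cell library sizes of a few thousand counts, records true
type and patient per cell, and can inject a mislabeled block of cells to
exercise the pseudo-bulk QC. It emulates annotation structure, not
single-cell measurement physics (no dropout model, no ambient RNA).
Consequently, green tests here certify the *bookkeeping and statistics* of
the benchmark — not that any solver will reach the same accuracy on real
tumors, where reference/mixture mismatch dominates.

## Ground-truth composition samplers

**Broken stick on a grid.** `broken_stick` partitions a total proportion
`p` across `n` populations. Every population is first allotted its
effective minimum (`max(min_prop, min_c)`, default floor 1%), and the
remaining slack is split by `n − 1` boundaries drawn uniformly from the
`step` grid (default 0.01; 0.001 for the in silico validation and spike-in
designs). In the continuous limit this equals the uniform stick partition
conditioned on every segment reaching its minimum — the conditional law of
a flat Dirichlet restricted to a shifted simplex — while remaining exact on
the grid. We chose allocation-then-slack over rejection because rejection
against the floor has vanishing acceptance in tight designs: with cancer
fixed at 0.65, a signal type at ≥ 0.2 and twelve backgrounds at ≥ 0.01, the
feasible slack is 0.03 and the acceptance probability of a naive rejection
sampler is of order 1e-13. Upper bounds `max_c` are still enforced by
rejection, where acceptance stays workable.

**Hit-and-run MCMC.** Biologically constrained compositions are uniform
draws from the polytope {x ≥ 0, Σx = p, min ≤ x ≤ max}. The bounds come
from a hierarchical constraint model — a tree whose nodes carry min/max
proportions *relative to their parent* (whole admixture → cancer /
leukocyte / stromal compartments → leaf populations) — flattened by
multiplying bounds down each path into one absolute inequality pair per
leaf. Two illustrative models ship as YAML (one styled on bulk pan-cancer
compartment surveys, one on single-cell tumor atlases; the values are
synthetic) and are combined by taking the wider bound per node, flooring
minima at 0.01. The sampler itself runs in compiled code: isotropic
directions inside the sum-zero hyperplane (Marsaglia-polar normals driven by
R's RNG, so `set.seed` governs chains exactly), chord endpoints from the box
constraints, a uniform step along the chord; chain length defaults to
1000·n³ with thinning n³. The starting point is the convex combination of
the lower- and upper-bound vertices meeting the sum constraint — an interior
point whenever the polytope has volume. Populations pinned by min = max are
factored out before sampling. On the unconstrained 3-simplex the thinned
chain reproduces the flat-Dirichlet Beta(1, 2) marginal moments within
Monte-Carlo error (a acceptance-suite check).

**Extremal selection.** Candidate pools are diversified by picking the pair
with maximum sum of squared differences, then greedily adding the candidate
maximizing its minimal squared distance to the selected set, ties to the
lowest index. When selection rotates through signal/decoy pools, the first
pick of an empty set is the candidate farthest from its pool mean — except
when a single pool supplies both opening rounds, in which case its exact
max-distance pair is taken.

## The eight-dataset validation layout

`assemble_challenge_layout` emits the full design: per in vitro-style
dataset (DS1–DS4, alternating cancer backbone × vendor batch) 15 biological
admixtures with the tumor proportion pinned to a value from the 0.20–0.80
grid (0.01 steps, sampled without replacement per dataset) plus 9 of 36
signal/decoy unconstrained admixtures; per in silico-style dataset
(AA/AB/AE/AF) 15 unconstrained admixtures at step 0.001 and 20 biological
admixtures taken as the 4 most distant of each of 5 independent chains.
Signal/decoy designs pin a signal type into [0.2, 0.35], exclude its decoy
partner entirely, bound other types by [0.01, 0.5], and draw the cancer
proportion from one of three windows ([0.2, 0.3], [0.4, 0.5], [0.6, 0.7]) as
a fixed extra slot; window values that leave less than the non-cancer minima
(cancer above 0.68 on this panel) are arithmetically unattainable and are
excluded. The assembled layout totals 96 in vitro-style and 140 in
silico-style admixtures with at least 18 per dataset.

## Mixing, spike-ins and pseudo-bulk

Admixture expression is a proportion-weighted sum of purified profiles in
linear space — TPM directly, or counts first equalized to pseudo-counts by
scaling every sample to the median library size. The profile representing a
type is matched to the admixture's batch label, so vendor structure
propagates into mixtures. Spike-in series place a target type at 49 levels
(0–0.1% step 0.01%, 0.1–1% step 0.1%, 1–20% step 1%, 20–40% step 2%) over
`n_reps = 10` reusable unconstrained backgrounds; coarse targets split their
fixed proportion across sub-populations with a flat Dirichlet(1/m). The
pseudo-bulk builder sums raw single-cell counts per (patient, annotation),
equalizes pair totals, weights by within-patient annotation frequency,
scales to CPM, and flags (patient, type) profiles whose k nearest neighbors
(default 10) in a 2-D embedding vote for a different annotation, excluding
the affected patients. The default embedding is PCA of log1p-CPM profiles;
any function returning two coordinates per profile can be plugged in, since
the QC rule only needs a neighborhood structure.

## Deconvolution cores

The four baseline cores share a signature interface built by
`build_signature`: per type, genes ranked by own/other mean fold change
(minimum 2), up to 20 markers, genes qualifying for several types dropped.

* Constrained (weighted) least squares minimizes Σ w_m (a_m − s_m·β)² with
  β ≥ 0 and Σβ ≤ 1. The sum constraint is encoded by a slack population and
  a heavily weighted equality row inside a non-negative least-squares solve;
  the penalty weight starts at 10³ × the scaled signature magnitude and
  steps down tenfold if the active-set solver stalls (a pure conditioning
  safeguard — the solution is insensitive across this range, and a grid
  search oracle confirms boundary cases).
* ν-SVR z-scores the admixture over the markers and the signature as a
  whole, fits a linear ν-support-vector regression per sample for
  ν ∈ {0.25, 0.5, 0.75}, keeps the lowest-RMSE fit and clips negative
  coefficients. The ν grid is our choice; the approach leaves ν selection
  open and this mirrors common practice.
* Huber robust regression is IRLS with weights 1 for |e| < k and k/|e|
  otherwise (k = 1.345 residual-scale units, the classical 95%-efficiency
  constant). An exact fit is returned as ordinary least squares directly,
  since the MAD scale estimate degenerates at zero residuals and the Huber
  and OLS solutions coincide there anyway.
* Marker summaries score a type as the mean (or sum) of its markers' linear
  expression — homogeneous of degree 1 in the admixture, hence
  cross-sample-comparable only.

Every method returns a `prediction_table` tagged `score`, `normalized`,
`fraction` or `proportion`; within-sample metrics refuse score-scale tables,
because raw enrichment scores are not comparable across cell types. An
`oracle_method` returning the ground truth anchors the harness: its
hierarchical score is 1, its spillover 0, and its limit of detection the
smallest nonzero grid level.

## Scoring, comparison and robustness statistics

The hierarchical score correlates prediction with truth per (dataset, cell
type), averages over cell types, then over datasets — so small datasets and
rare cell types carry the same weight as large ones, and a pooled
correlation would not be equivalent. Zero-variance predictions yield
undefined correlations; these are recorded as missing, excluded from the
cell-type mean and counted, a policy the degenerate-predictor tests pin
down. Method pairs are compared by bootstrap: sample indices are resampled
with replacement within each dataset, one shared draw per iteration applied
to both methods and the truth (paired comparison), and the Bayes factor
K = #(S_a > S_b)/#(S_b > S_a) with K > 3 significant. With a zero
denominator K is ∞ when the numerator is positive and 1 when both counts
are zero. Ranking orders by the Pearson-based score and re-orders the tie
group with the top method by the Spearman-based score.

Specificity: predictions on purified samples are min–max normalized per cell
type (degenerate constant columns set to 0 and flagged), and spillover into
X is the mean normalized prediction on samples purified for Y ≠ X — making
the measure invariant to any positive affine rescaling of a method's output.
Sensitivity: per spike-in level, a two-sided Wilcoxon rank-sum test against
the 0% baseline at raw α = 0.01; the limit of detection is the least level
from which *every* level upward is significant (a single interior
non-significant level pushes the LoD above it). `stats::wilcox.test`
supplies the exact null for small untied samples and the tie-corrected
normal approximation otherwise. Cross-dataset effects center each method's
per-dataset correlations, fit response ~ 0 + dataset, take one-sided
lower-tail p-values and adjust across all (dataset, cell type) tests with
Holm–Bonferroni, which needs no independence assumption; a perfect fit with
zero residual variance maps a zero coefficient to p = 0.5.

## Reproducibility, problem sizes and limitations

All randomness flows from explicit seeds; `run_config` derives one stage
seed per pipeline stage from a master seed, and `run_pipeline` writes TSV
artifacts plus a provenance log carrying the seed and a configuration hash.
Re-running a configuration reproduces every numeric output exactly; stages
toggled off re-read their cached artifacts.

The package's own test and acceptance runs use the full eight-dataset
layout (236 designs, hit-and-run chains of up to 1000·14³ iterations),
1000-sample chains for the moment checks, ten replicates per spike-in
level, and reduced sizes elsewhere (e.g. 300–1200 genes, bootstrap counts
of 20–200 in unit tests); the pipeline default is a compact four-dataset
design with `use_full_layout = TRUE` enabling the complete layout. These
sizes are package choices balancing statistical resolution against an
interactive workflow.

Known limitations: the expression model has no gene–gene correlation beyond
markers, no dropout or ambient contamination in the single-cell fixture, no
read-level simulation, and the shipped constraint bounds are illustrative
rather than estimated from cohort data. The benchmark therefore measures
algorithmic behavior under its stated generative model; transport to real
tumor data depends on reference quality and batch structure that this
harness intentionally controls away. Command-line orchestration is provided
through R functions and `scripts/acceptance.R` rather than a shell tool, as
the package's users work from R.
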