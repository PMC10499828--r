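---
title: "Methods: cell-frequency tumor-microenvironment subtyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-frequency tumor-microenvironment subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmesubtype)
```

# Overview

`tmesubtype` implements a multi-step analysis of multiplexed-imaging
single-cell data from triple-negative breast cancer (TNBC) tissue, of the kind
produced by cyclic immunofluorescence (CyCIF) on mouse tissue microarrays or
multiplexed ion beam imaging (MIBI) on human cores. The chain is:

1. **QC and gating** — remove DAPI-negative cells (tissue loss), subtract
   per-core background on high-background markers, and assign each cell to a
   lineage by thresholded marker positivity in a fixed priority order.
2. **Cell-frequency subtyping** — summarize each core as an
   epithelial/immune/stromal fraction vector, cluster cores on a k-nearest
   neighbour graph with the Leiden algorithm, collapse clusters by centroid
   correlation, and annotate the three microenvironment subtypes: stromal-poor
   (SP), stromal-rich-immune-rich (SR-IR) and stromal-rich-immune-poor
   (SR-IP).
3. **Spatial compartment profiling** — build a tumor mask per core from
   epithelial (PanCK-class) versus immune (CD45-class) cell density, split the
   core into periphery / border / core compartments, and compute cell-type
   densities (cells/mm²) and their z-of-log10 transform.
4. **Molecular subtype calling** — normalize bulk counts, map a human TNBC
   centroid signature (BLIA / BLIS / LAR / MES) to mouse genes through an
   ortholog table, and call each sample's subtype by Spearman correlation to
   the z-scored centroids.
5. **Statistics** — Kaplan–Meier curves, the weighted log-rank family
   (standard log-rank and the Gehan–Breslow–Wilcoxon n-at-risk weighting),
   Pearson chi-squared association, odds ratios, and the caliper tumor-volume
   formula $V = L \cdot S^2/2$.

Every stage is exercised against a synthetic cohort generator with known
ground truth, so the full chain is testable with no external downloads.

# Gating model

Cells are partitioned exhaustively and mutually exclusively, in priority
order:

| priority | rule | lineage |
|---|---|---|
| 1 | CD31⁺ | endothelial |
| 2 | ≥1 of Ecad, EpCAM, CK5 positive, CD31⁻ | epithelial |
| 3 | CD45⁺, CD31⁻, epithelial-marker negative | immune |
| 4 | everything else | stromal |

The order matters: a CD31⁻ Ecad⁺ CD45⁺ double-positive is epithelial, not
immune. For *fallback cores* — tumors whose malignant cells lack all canonical
epithelial markers — tumor cells are defined negatively: any cell negative for
the full stromal/immune gating set (CD31, CD45, Vim, aSMA, ColIV, ColVI,
Gal3) is called epithelial. The published description of that marker list
contains a duplicated "ColIV"; we read it as ColIV and ColVI, both present in
the stated antibody panel.

**Positivity** is strict (`intensity > threshold`). Thresholds in the original
workflow were set manually per marker and are not published; the package
accepts user thresholds and offers `auto_threshold()`, an Otsu-style
between-class-variance maximizer, as a reproducible default. Two numerical
choices matter and were found the hard way:

* thresholding is done on the `log10(x + 1)` scale, which symmetrizes the
  log-normal positive/negative components and keeps the cut stable when the
  positive population is rare (a raw-scale Otsu collapses onto the bulk of the
  negatives when positives are < ~5%);
* when the pipeline auto-thresholds background-subtracted markers it excludes
  values clamped to exactly zero — the clamp spike is otherwise mistaken for a
  second mode;
* on an optimum *plateau* (empty histogram gap between components) the
  midpoint of the plateau is returned, so the threshold lands between the
  modes rather than at the gap's edge.

**Background subtraction.** The published pipeline subtracts interpolated
autofluorescence in image space, which is out of scope for a single-cell
table. The table-level stand-in is a per-core location estimate of the
marker's intensity distribution — by default the 20th percentile — subtracted
and clamped at zero. The estimator is a function argument and can be replaced.

# Subtyping model

Per-core compositions are fractions over {epithelial, immune, stromal};
endothelial cells are rare and merged into stromal. Cores are clustered with
`igraph::cluster_leiden` (modularity objective with a resolution parameter,
i.e. the RB-Potts-style family) on a symmetric 15-nearest-neighbour Euclidean
graph. 15 neighbours is the only neighbourhood size stated in the source
workflow (for single-cell clustering) and is reused at core level; it is a
config key. Defaults per platform preset: fixed resolution 0.5 for mouse
cores (chosen in the original workflow because it captured the histological
subtypes — a supervised judgment call this package does not attempt to
reproduce), 0.1 for the human MIBI panel, 0.6 for detailed single-cell
clustering on the 20-marker + 2-morphology feature matrix.

Alternatively `select_resolution()` evaluates a resolution grid (default
0.2–0.5) and picks the maximum mean silhouette width (Euclidean distance in
feature space; ties to the lowest resolution). "Point of diminished returns
for silhouette width" is not a formula; argmax of the mean silhouette is our
operationalization, and the full trace is kept so a user can apply their own
elbow judgment.

Raw clusters are collapsed to three by hierarchically clustering cluster mean
composition vectors on correlation distance (1 − Pearson, average linkage)
and cutting at k = 3. Annotation is rule-based: highest mean epithelial
fraction → SP; of the rest, higher mean immune fraction → SR-IR, lower →
SR-IP. An optional SP⁺ flag marks the SP-member raw cluster with the lowest
stromal fraction. `consensus_label()` implements the companion 80%-agreement
rule for propagating lineage annotations to clusters (inclusive threshold:
16/20 agreement is enough; 15/20 is "mixed").

A deliberate limit of the graph approach: under a vanishing resolution the
partition converges to the *connected components* of the kNN graph, so
well-separated islands never merge into one cluster; the single-cluster limit
holds only on connected graphs.

# Spatial model

Masks are rasterized at 50 µm (config key): grid cells with ≥1 epithelial
cell, morphologically closed with a one-cell radius, minus cells where immune
count exceeds epithelial count. The border is every point within 100 µm
(config key) of the mask boundary, on either side; core and periphery are the
remainders inside and outside. Neither the grid size, the band width, nor the
exact mask rule is published — all are documented configuration decisions.
Distance to the boundary is approximated by the distance to the nearest
grid-cell centre of opposite mask state (half-cell accuracy). Cells inherit
their grid cell's compartment, which makes the conservation identity exact:
summed `density × area` over compartments equals the retained cell count,
integer for integer.

Densities are reported per mm² (1 µm² = 10⁻⁶ mm²). The heatmap transform is
the z-score (sample sd) of `log10(density + 1)` per cell type across
compartments × cores; the pseudocount of 1 cell/mm² keeps empty compartments
finite.

# Expression model

Size factors are median-of-ratios (geometric-mean-1 convention). The full
variance-stabilizing transform of a count model requires a fitted dispersion
trend, which is out of scope; the stand-in is
`log2(count / size_factor + 1)`. This matters less than it may appear:
subtype calling is Spearman-based, and the tests verify that calls are
invariant when the stand-in is replaced by other strictly monotone
transforms.

The centroid panel shipped with the package is **synthetic**: the published
77-gene human TNBC centroid table and the live ortholog database it was
mapped through are external resources, so `inst/extdata` carries a synthetic
77-gene centroid table and an ortholog map covering 60/77 = 78% of it, which
reproduces the structure (including the mapped fraction) without claiming the
published values. Whether the published centroids were re-z-scored after the
77→60 filtering is unstated; this package re-z-scores per gene across
subtypes after filtering, and flags that choice here. One-to-many ortholog
mappings resolve to the first listed pair with a warning.

Two small expression-side rules are implemented verbatim: the DE signature
filter (`Log2FC > 1.5` and `padj < 0.05`, both strict), and the
display-convention PC scaling that divides each component's scores by its
proportion of variance — the latter inflates minor components and is flagged
as unusual; numerically-zero components are dropped before the division.

# Survival and association statistics

Kaplan–Meier estimation is the product-limit formula. The weighted log-rank
family accumulates observed-minus-expected event counts over distinct event
times with weight 1 (log-rank) or the number at risk (Gehan–Breslow–
Wilcoxon, Breslow's generalization of the named test), using the
tie-corrected hypergeometric covariance, and refers the quadratic form on
k − 1 groups to χ²(k − 1). Note a finite-sample fact checked in the test
suite: the hypergeometric variance is *not* the exact label-permutation
variance (on an 8-record all-events fixture they differ by ~9%); the
package implements the standard estimator and the tests verify it against an
independent brute-force recomputation, against `survival::survdiff`, and
against the exhaustive permutation distribution for calibration.

The odds ratio accepts either a 2×2 table or two printed proportions; the
proportion route, `(p1/(1−p1))/(p2/(1−p2))`, is what reproduces a published
ratio quoted from rounded percentages (77% of 101 vs 45% of 198 gives 4.09 →
4.1; reconstructing integer cells first gives 4.15). A 0.5
continuity correction for zero cells is opt-in and flagged in the result.
The tumor-volume caliper formula `L·S²/2` tops out at 4000 mm³ at the 2 × 2
cm institutional limit; `volume_threshold_records()` converts growth curves
to time-to-threshold survival records (the convention for feeding growth
data to a survival test is this package's choice, as the original is
unstated).

# The synthetic cohort: what it emulates, and what it does not

`sim_config()` states the simulated world once:

* **Geometry.** Each core is a 1.5 mm-diameter disk (the stated TMA core
  size) with a concentric 500 µm tumor nest and a 100 µm border band.
* **Composition.** Fixture defaults (the source figures are graphical, so
  these are *not* published numbers): SP 0.80/0.07/0.13,
  SR-IR 0.45/0.30/0.25, SR-IP 0.45/0.05/0.50 over
  epithelial/immune/stromal, with 0.02 of the stromal share assigned to a
  rare endothelial lineage — without it the CD31 channel has no positive
  population and no threshold is meaningful.
* **Infiltration.** Immune cells are placed across compartments with density
  multipliers periphery:border:core = 4:2:1, reproducing the observed
  gradient (immune density lowest in the tumor core); epithelial cells fill
  the nest, stromal/endothelial the surrounding annulus.
* **Intensities.** Two-component log-normal per marker (meanlog log 2 vs
  log 20, sdlog 0.4), with a constant-per-core additive background on
  flagged markers (CD31, CD45, ColIV) — reproducing the clamping behaviour
  the background-correction code must handle. 2% of cells are emitted
  DAPI-negative, the scale of the stated QC filter.
* **Expression.** Negative-binomial counts (dispersion 0.1, a typical bulk
  RNA-seq biological CV); signature genes shift toward the sample's true
  centroid by `centroid_shift` units of the gene's marginal log2 sd (delta
  method), so "a 2-sd shift" means literally that.
* **Survival.** Exponential event times with per-subtype hazards (defaults
  0.02, 0.004, 0.008 events/day for SP, SR-IR, SR-IP — SP worst, consistent
  with the observed prognosis ordering; median survival 35, 173, 87 days)
  and independent uniform censoring over a 365-day window.

What a green test does **not** establish: cells are points with feature
vectors, not pixels — no segmentation error, no marker spillover or spatial
intensity artifacts, no irregular tumor-nest shapes, no spatial correlation
between neighbouring cells' intensities, and bulk samples are independent of
the imaged cells rather than the same tissue. Recovery results on this
generator are a correctness check of the pipeline's logic, not a performance
claim about real tissue.

# Reproducibility

All generators funnel randomness through explicit integer seeds and restore
the caller's RNG state; `run_pipeline()` derives its stage seeds from one
master seed and records every default actually used (thresholds, resolution,
band width, seeds) in its run report. Configuration files are JSON
(`read_pipeline_config()`); YAML is deliberately not a dependency.
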