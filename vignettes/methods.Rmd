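---
title: "Methods: maximum-entropy habitat modeling in entsdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy habitat modeling in entsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`entsdm` estimates a presence-only species distribution by maximum
entropy. The landscape is a finite set of grid cells; the model is a Gibbs
density over the background cells,

$$ q_\lambda(x) = \frac{e^{\eta_\lambda(x)}}{\sum_{x' \in \mathrm{bg}} e^{\eta_\lambda(x')}},
\qquad \eta_\lambda(x) = \sum_j \lambda_j f_j(x), $$

where the $f_j$ are features derived from the environmental layers.
Coefficients maximize the L1-penalized presence log-likelihood

$$ J(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \eta_\lambda(x_i)
  - \log \sum_{x \in \mathrm{bg}} e^{\eta_\lambda(x)}
  - \sum_j \beta_j |\lambda_j|. $$

This is the classical MaxEnt formulation: the penalized maximum-likelihood
Gibbs density is also the maximum-entropy distribution subject to relaxed
feature-expectation constraints, with the relaxation widths $\beta_j$
acting as the regularization. At an optimum, any feature with
$\lambda_j \neq 0$ or $\beta_j = 0$ satisfies the moment condition
$\mathbb{E}_{q_\lambda}[f_j] = \bar f_j^{\mathrm{presence}}$ (tested
directly as a KKT check).

**Feature classes.** Linear, quadratic, pairwise product, hinge (forward
and reverse ramps at evenly spaced knots), and threshold (step indicators)
features, selected by a feature-class string such as `"LQHPT"`. Every
feature is min–max scaled to $[0,1]$ using its background distribution;
knots are placed strictly inside each layer's background range. Defaults
are 50 hinge knots per direction and 20 thresholds; analyses in the tests
and the acceptance run use fewer (8 and 6) because on smooth synthetic
fields the response surfaces are low-frequency and the extra knots only
add runtime.

**Regularization.** Per-feature penalties follow the published schedule:
a class-specific base value interpolated in the presence count
(linear/quadratic/product $1.0 \to 0.2 \to 0.05$ at $10/30/100$
presences; hinge $0.5$; threshold $2.0 \to 1.0$), multiplied by the
feature's background standard deviation, divided by $\sqrt{m}$, and
scaled by the global regularization multiplier (RM). Larger RM gives
sparser models; the non-zero coefficient count is non-increasing in RM
(a tested invariant).

**Solver.** Cyclic coordinate descent with soft-thresholding: each pass
takes a one-dimensional Newton step on the smooth part of $J$ for each
feature, applies the L1 shrinkage, and step-halves until the objective
does not decrease, so $J$ is monotone non-decreasing across updates.
Iterations are full cycles; fitting stops when a cycle improves $J$ by
less than `tolerance` (default $10^{-7}$) or at the ceiling (default
500 cycles, a deliberate overfitting guard as much as a cost cap).
Coefficients start at zero, which makes the accumulated per-feature
objective gains a natural training trace: percent contribution per
variable is the normalized sum of the gains of its features, with
product-feature gains split evenly between the two parents. The trainer
is validated against an independent generic convex solver (L-BFGS-B on
the split $\lambda = \lambda^+ - \lambda^-$ reformulation) to
$10^{-4}$ in objective on small problems.

**Output scales.** `raw` is $q_\lambda$ itself (sums to 1 over the
background). `logistic` is $\sigma(H + \eta - \log Z)$ with $H$ the
entropy of the fitted background distribution — the standard 0.5-prevalence
logistic index, equal to 0.5 everywhere for an uninformative model.
`cloglog` is $1 - \exp(-e^{H + \eta - \log Z})$. Projection onto new
layers clamps inputs to the training range (features to $[0,1]$), the
standard MaxEnt transfer behavior; clamp counts are reported per layer.

## The pipeline around the engine

* **Occurrence preparation.** Cleaning drops unparseable coordinates,
  collapses exact duplicates (first in input order wins), and optionally
  drops records older than a cutoff year while keeping undated ones.
  Spatial thinning keeps one record per bucket of a regular lon/lat grid
  anchored at $(-180°, 90°)$; the default bucket is 30 arc-seconds
  (≈1 km). A grid rule was chosen over a pairwise-distance rule because
  it is deterministic, order-stable, and idempotent; the "most
  representative" record per cell is undefined in common usage, so the
  first record in input order is kept.
* **Screening.** A trial model with default settings (RM = 1, FC = LQH)
  supplies percent contributions; layers below a contribution floor are
  dropped, then a greedy filter visits layers by descending contribution
  and accepts a layer only if its absolute Pearson correlation with every
  accepted layer is ≤ 0.85. The greedy order implements "priority to the
  higher-contribution member" and guarantees a conflict-free, maximal
  set. Correlations are computed over the presence + background sample
  (the convention of the common screening tools), not all cells;
  `pearson_matrix` accepts any matrix if all-cell screening is wanted.
* **Tuning.** One fit per (RM, FC) candidate on the full occurrence set —
  the AICc-selection convention — over RM ∈ {0.5, …, 4.0 step 0.5} × FC ∈
  {L, H, LQ, LQH, LQHP, LQHPT} by default (48 candidates). The raw
  prediction is renormalized over all valid landscape cells;
  $\mathrm{AICc} = 2k - 2\ln L + 2k(k+1)/(n-k-1)$ with $k$ the non-zero
  coefficient count. Rows with $n - k - 1 \le 0$ are flagged undefined and
  excluded from selection. The ΔAICc = 0 row wins; ties break by fewer
  coefficients, then smaller RM, then feature-class list order. A
  held-out AUC per row can be reported for reference but never drives
  selection.
* **Evaluation.** AUC is the exact Mann–Whitney statistic on presence vs
  background scores (ties = ½). TSS is maximized over every distinct
  observed score used as a `>=` threshold, ties resolved toward the
  lowest threshold; background points are the negative class for both —
  the presence-only convention, stated explicitly because external
  protocols often leave the negative class implicit. Bootstrap
  evaluation resamples presences with replacement, splits 75/25, fits,
  scores the held-out quarter, and averages predictions cellwise over 10
  replicates by default.
* **Habitat accounting.** Suitability is classified by fixed breaks
  0.1/0.3/0.5 (unsuitable/low/moderate/high, half-open intervals,
  boundary values going up); exact Fisher–Jenks natural breaks (dynamic
  programming, brute-force-verified) are available as the data-driven
  alternative. Cell areas use the spherical-zone formula with the
  authalic radius 6371.0088 km. Change maps binarize at suitable =
  {low, moderate, high} and report gain, loss, both stable classes, and
  *both* the gross turnover (gain + loss) and the signed net change
  (gain − loss), since "net change" is ambiguous in common usage; the
  print method labels each explicitly. Centroids are area-weighted means
  of cell centers over the binary high class (a suitability-weighted
  variant is available via `weight_by`); shifts use the WGS84 ellipsoidal
  inverse geodesic — back-calculation against published centroid pairs
  favors it clearly over the spherical haversine, which is provided as a
  documented fallback (within ~0.5%). Shift directions use
  cardinal-quadrant labels (any north + west displacement is "NW"), which
  matches how such shifts are described in practice.

## The synthetic landscape

Real occurrence archives and climate rasters cannot ship with a package,
so every downstream stage is exercised on landscapes with a known truth:

* Layers are Gaussian random fields: white noise convolved with a
  Gaussian kernel of standard deviation `corr_length` cells (FFT,
  circular), standardized to mean 0, variance 1. The kernel construction
  is simple and gives direct control of autocorrelation
  (`corr_length = 0` is white noise; 20 gives lag-1 autocorrelation
  above 0.95).
* Cross-correlation between layers is imposed by empirically whitening
  the independent fields (centering + QR orthonormalization across
  cells) and mixing through the symmetric square root of the target
  correlation matrix, so empirical correlations match the target to
  numerical precision — including degenerate targets (r = 1 duplicates a
  layer), which is exactly what collinearity screening needs to be
  tested against.
* The species truth is a linear–quadratic predictor through the logistic
  function (logistic, not cloglog, so the truth is on the same scale as
  the default output). Quadratic coefficients must be ≤ 0: unimodal
  responses with optimum $-b/(2a)$.
* Presences are drawn cell-by-cell without replacement with probability
  proportional to suitability — one record per cell, mirroring the
  thinning convention downstream.
* "Future" stacks are additive shifts of named layers.

The packaged default scene has ten layers named after common SDM
predictors, two r = 0.9 pairs to exercise screening, and a niche driven
by four layers with dry-month precipitation dominant. The niche optima
sit away from the layer means with narrow response widths, so presences
concentrate in a restricted region and fitted models reach the
high-discrimination regime (AUC ≈ 0.9) of a well-determined SDM; with
optima at the layer means and broad widths, most of the landscape is
moderately suitable and no model can discriminate well — a property of
the scene, not of the estimator.

What the generator does *not* emulate: sampling bias, coordinate error,
non-stationary spatial covariance, interactions in the truth (the truth
is additive), categorical predictors, and dispersal limitation. Passing
the recovery tests therefore shows the estimator and pipeline are
correct and well-calibrated on smooth, unbiased landscapes; it does not
certify performance on biased archival data.

## Numerical choices and degenerate inputs

* Coordinate convention: north-up, square cells, 0-based row/col
  internally documented as half-open intervals; a point on a cell edge
  belongs to the cell to its east/south. This removes every boundary
  ambiguity from extraction, thinning, and AICc occurrence lookup.
* Background sampling is uniform over valid cells *without* replacement
  (at most one point per cell); requests beyond the valid-cell count
  return all cells with a warning.
* Constant layers contribute no features (warning); constant columns get
  correlation 0 (warning) rather than NaN.
* `sample_matrix` rows never contain missing values; points on nodata
  cells are dropped with a logged count before construction.
* ESRI ASCII grids are written with 17 significant digits, so write/read
  round-trips reproduce IEEE doubles exactly. GeoTIFF is declined with
  an informative error rather than read without its georeferencing.
* All stochastic stages derive per-stage sub-seeds from one master seed
  (`stage_seed`), giving byte-identical artifacts for identical
  config + seed (tested).
* An empty suitable area flags percentages as undefined instead of
  propagating NaN; an empty target class is an error for centroids.

## Problem sizes

The test suite runs scenes between 20×20 and 60×60 cells with 150–800
background points, chosen so the full suite completes in seconds while
every oracle comparison stays exact. The acceptance script runs the
packaged 200×200 scene with 10,000 background points and 10 bootstrap
replicates, with the 48-model tuning grid evaluated on a 60×60 version
of the same scene at 2,000 background points — tuning needs relative
AICc ranks, which stabilize at far smaller sizes than predictions do.

## Known limitations

* The solver is plain R; very large feature expansions (hundreds of
  hinge knots × many layers at 10⁴ background points) are slow. The knot
  counts are the main cost lever and the defaults are conservative.
* Only geographic (lon/lat WGS84) grids are supported: no projected
  CRSs, rotated grids, or vector data.
* Soil-class-like ordinal predictors are treated as continuous; there is
  no categorical feature class.
* Percent contribution is path-dependent (it reflects the training
  trajectory); permutation importance is the more robust ranking and is
  what the recovery checks use.
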