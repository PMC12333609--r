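---
title: "Dual-engine presence-only habitat suitability modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-engine presence-only habitat suitability modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duosdm)
```

## The problem

Coastal cetacean populations are often known only from presence records:
sightings collected on survey tracklines plus opportunistic reports from sea
users, with no usable absences and strongly uneven observation effort.
`duosdm` implements a complete presence-only habitat-suitability pipeline for
this situation, pairing two estimators with complementary assumptions — a
binomial generalized additive model (GAM) fitted to presences and
pseudo-absences, and a maximum-entropy (maxent) density estimator fitted to
presences and background points — over a small set of environmental and
anthropogenic predictor rasters (chlorophyll-a, SST anomaly, seabed slope,
distance to aquaculture installations).  Because the two engines make
different errors, agreement between their suitability maps is the usable
conservation signal, and each map carries a per-cell uncertainty companion.

Everything runs on a synthetic coastal landscape with known true
suitability, so every stage of the pipeline — bias-corrected background
sampling, predictor screening, tuning, cross-validation, importance,
uncertainty, and the citizen-science ablation — is testable end-to-end
without any external data product.

## The raster layer

All spatial layers share one minimal container, `rast_grid`: a numeric
matrix (row 1 = north), pixel sizes in meters (rectangular pixels are
supported), a free-text CRS tag, and `NA` as nodata.  Derived predictors are
computed in-package:

* **Slope and aspect** by Horn's 8-neighbor finite differences; slope in
  degrees, aspect as the downslope direction clockwise from north.  Cells
  whose 3x3 neighborhood touches nodata (including the grid border) are
  nodata, and flat cells have undefined aspect (nodata).
* **Distance surfaces** as exact Euclidean distance from cell centers to
  point features or to polyline/polygon *boundaries* (not filled
  interiors).
* **Temporal means** of daily layers are nodata-aware: a cell is averaged
  over the days it is observed and is missing only if missing every day.
* **Resampling** onto a target grid is bilinear for continuous fields
  (weights renormalized over valid corner cells; no extrapolation beyond
  the source cell-center hull), with nearest-neighbor available for
  categorical layers.

Rasters are exchanged as ESRI ASCII grids (the plain-text AAIGrid dialect,
with `dx`/`dy` keywords when pixels are rectangular) plus a `.prj` sidecar
carrying the CRS tag; vector features travel as GeoJSON or WKT.

## The synthetic study system

`generate_landscape()` builds a 120 x 180 grid of 250 m cells whose valid
region is a wavy alongshore band 14 cells (3.5 km) wide — about 157 km^2,
the scale of a small coastal Special Area of Conservation.  Depth increases
offshore to ~100 m at the band's outer edge; slope is derived from the full
(unmasked) depth surface so the band has no derivative edge loss.  Four
"aquaculture" point attractors sit ~1 km offshore.  Chlorophyll-a is a
positive baseline field plus exponential-decay bumps centered on the
attractors (`0.15 + 0.3*exp(0.8*Z) + 0.35*exp(-d/1500)`), which guarantees
the negative chlorophyll-distance coupling observed around fish farms.  SST
anomaly is an independent smooth field.  Smooth fields are seeded white
noise convolved with a Gaussian kernel — simpler and more portable than
variogram simulation.

True suitability is an inverse-logit index over standardized predictors:

$$\eta = \beta_{chl} z_{chl} - \beta_{sst} z_{sst}
      - \beta_d \, d/\sigma_d
      + \alpha \exp\!\big(-(s - s_0)^2 / 2w^2\big) + \beta_0 .$$

Default coefficients (chosen once, at design time) are
$\beta_{chl} = 4$ per SD — twice every other effect
($\beta_{sst} = \beta_d = \alpha = 2$) — with $\sigma_d = 5$ km,
a slope optimum $s_0 = 2.5°$ of width $w = 1°$, and intercept
$\beta_0 = -3.5$.  Two design choices deserve explanation:

* **Hotspot regime.** The intercept puts the median cell near suitability
  0.02 with localized patches above 0.9.  Presence-versus-background
  discrimination (AUC) is bounded by how concentrated suitable habitat is:
  if suitability were moderate everywhere, even the *generating* surface
  could not exceed AUC ≈ 0.7 against any background sample.  Coastal
  dolphin habitat in the emulated system is exactly this kind of localized
  hotspot structure.
* **Fine-scale chlorophyll.** The chlorophyll baseline uses a short
  correlation length (1.5 cells ≈ 375 m) while SST anomaly and depth noise
  use 10 cells.  Under a target-group background design the background
  inherits the *spatial* pattern of the presences, so only habitat
  variation at scales finer than the bias-surface kernel remains
  separable from sampling density; remotely sensed coastal chlorophyll is
  indeed patchy at sub-kilometer scales, unlike mesoscale SST anomaly.

`sample_occurrences()` draws presence cells without replacement with
probability proportional to truth x detection bias and jitters points inside
cells.  The default detection surfaces are a trackline corridor along the
west-central shore (the "survey" platform) and a harbor-centered hotspot in
the east (the "citizen" platform): spatially complementary by construction,
which is what gives the ablation experiment a genuine coverage gap.  The
default dataset is 20 survey + 49 citizen = 69 records, with group sizes of
1 + Poisson(3.8) so that ~4.1 groups and ~20 individuals per 100 km of
trackline correspond to the emulated survey effort.

## Sampling bias and background selection

`build_bias_surface()` estimates relative observation effort from the
occurrences themselves: a Gaussian kernel density at cell centers, a 3x3
focal mean, a hard mask at zero outside the union of 2-km buffers around
occurrences and around the (dilated) study-area polygon, rescaling to
maximum 1, and a floor of 1e-6 inside the mask.  The floor is applied after
the rescale — applied before, it would be destroyed by the normalization and
reachable cells could end at weight zero.

The kernel bandwidth defaults to the isotropic normal-reference rule
$h = \sqrt{(\mathrm{var}(x)+\mathrm{var}(y))/2}\; n^{-1/6}$ (~4 km for 69
points spread along a 40-km band), not a fixed small value.  This matters:
at n = 69 a kernel much narrower than the point spread reproduces the
presence point pattern itself, so backgrounds drawn from it condition away
the very habitat signal the design is meant to preserve — even the
*generating* suitability surface scores near chance against such
backgrounds, while under the normal-reference bandwidth it retains its
discrimination.  The bandwidth remains a config setting for users who want
a tighter surface.

Background points are drawn *with replacement* at the cell level (a
30,000-point pool over ~2,500 valid cells necessarily repeats cells),
uniformly jittered within cells, and never de-duplicated.  Pseudo-absences
for the GAM are a seeded uniform subsample of the pool.

## The GAM engine

`fit_gam()` is a penalized-spline binomial GAM written from first
principles:

* **Basis.** Each smooth is a B-spline basis with exactly `k` functions on
  quantile-anchored knots spanning the training range (cubic for k >= 4;
  for k = 3 the order drops to 3 so the basis still sums to one on the data
  range — three cubic B-splines cannot).  Identifiability comes from
  centering basis columns over the training rows, so every partial response
  averages to zero over the design.
* **Penalty and shrinkage.** A second-order difference penalty (lambda)
  controls wiggliness; its null space (constant + linear trends) gets a
  second penalty (lambda0, the double-penalty construction), so a term can
  be shrunk entirely out of the model — the "shrinkage smoother" behavior
  that effects variable selection during fitting.
* **Fitting.** Penalized IRLS with a 1e-8 tolerance on the penalized
  deviance and a 200-iteration cap.  Both penalties per term are selected
  by minimizing GCV on the converged working model over a 21-point log grid
  (1e-4..1e4), coordinate-wise with two sweeps, re-converging IRLS between
  sweeps.  Perfect separation is flagged, not fatal (shrinkage
  regularizes).
* **Outputs.** Deviance accounting (AIC = deviance + 2 edf, edf = trace of
  the influence matrix), delta-method prediction standard errors on the
  response scale from the penalized-fit coefficient covariance, partial
  response curves with pointwise SEs, and leave-one-predictor-out
  deviance-drop importance (proportions may sum above 1 because reduced
  models re-select their penalties).

Prediction beyond a smooth's training range extends the basis linearly and
flags the cell in a coverage raster.  Two uncertainty modes are available:
the analytic SE map from the fit itself (the default), and an optional
resampling mode (`gam_resample_predict()`) that redraws pseudo-absences per
iteration; they answer slightly different questions and are labeled
accordingly.

## The maxent engine

`fit_maxent()` maximizes the L1-regularized training gain

$$G(\lambda) = \frac1m \sum_{i \in \text{pres}} \lambda^\top f(x_i)
  - \log Z(\lambda) + \log N - \sum_j \beta_j |\lambda_j|,
  \qquad Z = \sum_{\text{bg}} e^{\lambda^\top f(x)},$$

by cyclic coordinate descent with soft-threshold Newton updates and step
halving, so the gain is non-decreasing across updates (asserted per cycle
in the tests).  Features are linear, quadratic and hinge (forward and
reverse, 30 knots per direction at evenly spaced background quantiles), all
min-max scaled on the background to [0, 1]; product and threshold features
are never generated.  Per-feature regularization is
$\beta_j = \beta \, c_{class} \, s_j / \sqrt{m}$ with $s_j$ the presence
sample SD (floored at 1e-3) and $c_{class}$ = 1 for linear/quadratic, 0.5
for hinge — a simplified schedule that preserves the roles of the
regularization multiplier and the sample size.  "Iterations" is a cap on
full coordinate cycles (500 by default), matching its role in the reference
tool; fits that stop at the cap are used as-is.

The raw output is the fitted density over the background normalizer;
the logistic output is $e^H r / (1 + e^H r)$ with $H$ the entropy of the
fitted distribution, so the null model scores 0.5 everywhere.  At
$\beta = 0$ the fitted background expectations moment-match the presence
feature means (tested to 1e-4), and on tiny problems the coordinate-descent
solution matches brute-force maximization of the same objective to 1e-3.
Percent contribution credits positive gain increments to the updated
feature's parent predictor; permutation importance permutes one predictor
across the pooled rows and renormalizes the training-AUC drops to 100.
Uncertainty comes from bootstrap resampling of the presences (500
replicates by default) summarized as per-cell mean, SE of the mean, and CV.

## Screening, evaluation and tuning

* **Collinearity pruning** iterates on the worst pair with |Pearson r| >
  0.7 (computed over cells valid in all layers), resolving each pair by
  single-predictor GAM AIC (k = 5, matching the final models); AIC ties
  within 1e-6 fall back to keeping the lexicographically smaller name.
  Pairs are processed in descending |r|, and at most p − 1 removals can
  occur.
* **Concurvity** of each fitted smooth is the squared norm of the
  projection of its fitted contribution onto the span of the intercept and
  all other terms' columns, over its squared norm — 0 for orthogonal terms,
  1 for a term reproducible from the others.  Terms above 0.8 are flagged
  (removal is advisory; the pipeline's select stage drops them).
* **Metrics.** AUC is the exact Mann-Whitney statistic (ties at 1/2); TSS
  maximizes sensitivity + specificity − 1 over all threshold candidates
  (midpoints of adjacent distinct pooled scores plus ±infinity),
  classifying score >= threshold as positive and returning the smallest
  maximizing threshold.
* **Cross-validation** stratifies folds on the class label; folds that lose
  a class in test are skipped with a warning, never re-randomized.  The
  pipeline reports *repeated* stratified CV (3 repeats by default), each
  repeat redrawing the negatives from the pool: with 69 presences a single
  negative draw dominates the CV noise, and repeats estimate the same
  quantity more stably.
* **Tuning** sweeps k in {3, 5, 10} x 30 background counts drawn from
  30..250 for the GAM (50 repeats of a 90/10 stratified split in the full
  protocol) and beta in 1..5 x background counts from 1,000..12,000 for
  maxent.  The paper-gap here — published tuning narratives rarely state a
  selection rule — is codified as: among settings whose mean TSS is within
  0.02 of the maximum, take the highest mean AUC; ties prefer smaller k (or
  beta), then fewer background points.  The study presets (1:1 with k = 5;
  8,000 with beta = 1) are available without tuning, and the "30 values"
  drawn for the background-count candidates are read as 30 candidate
  *counts* sampled uniformly from the stated range (the other reading — 30
  fixed point subsets — would leave the count axis of the tuning curve
  unexplored).
* **Uncertainty maps** report, in replicate mode, the per-cell mean, the SE
  of the mean (sd/sqrt(R)), and CV = 100 * sd / mean — sd, not SE, in the
  CV numerator so the CV describes prediction variability rather than
  shrinking with the replicate count; both are emitted.  Analytic mode
  passes a (mean, SE) pair through with CV = 100 * SE / mean.  The two
  modes are not comparable and are labeled.
* **Ablation.** `ablation_citizen_science()` reruns the whole modeling core
  with survey records only, every setting held fixed, and reports per-run
  AUC/TSS, mean CV, the per-cell suitability difference, and (optionally)
  mean predicted suitability inside a region of interest such as the
  citizen-covered sector.

## Reproducibility

Every stochastic operation takes a seed; pipeline stages derive theirs
deterministically from one master seed via `derive_seed(master, stage,
counter)`, and seeded functions restore the caller's RNG state.  Running
`run_pipeline()` twice on one config gives bit-identical rasters.  The
manifest records the config, per-stage status and wall-clock times.

## Problem sizes

The packaged analyses and tests run at deliberately chosen sizes: the
default landscape (120 x 180 cells, ~2,500 valid), 69 presences, a
30,000-point pool, 3-repeat 10-fold CV for both engines, 10 tuning repeats
in the tuning driver (50 in the full protocol), 100 bootstrap replicates in
the fitting driver (500 by default in the API), and a reduced maxent
configuration (2,000 background points, 15 hinge knots per direction,
200-cycle cap) inside the ablation and importance-recovery studies.  These
sizes keep the test suite and the shorter drivers in the minutes range on a
single core (the bootstrap-heavy fitting driver takes a few tens of
minutes) while leaving every qualitative conclusion unchanged.

## What the synthetic tests do and do not show

The generator emulates the *structure* of a coastal presence-only study —
biased two-platform detection, target-group background correction, localized
habitat, a dominant productivity driver coupled to point attractors.  It
does not emulate observation error in the predictors, temporal dynamics
(within-season SST evolution, chlorophyll phenology), spatial autocorrelation
of detection beyond the two smooth effort surfaces, group-size-dependent
detectability, or positional error in reported sightings.  Passing tests
therefore demonstrate that the estimators and the pipeline recover known
structure under the stated sampling model — not that any particular field
dataset satisfies that model.  Known limitations: GCV-selected penalties are
noisy at n = 69 (the motivation for repeated CV); the maxent regularization
schedule is a simplified stand-in for the published defaults, so absolute
gain values are not comparable to the reference tool's; and distances are
planar, so grids must arrive in a projected CRS in meters.
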