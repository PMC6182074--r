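---
title: "Spectrum-effect modelling of multi-herb decoctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-effect modelling of multi-herb decoctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectreff)
```

## The problem

A decoction of several botanical drugs inhibits an inflammatory readout —
here CCL17 secretion by TNF-α/IFN-γ-stimulated keratinocytes — and the
question is which of its dozens of constituents carry that activity.
Spectrum–effect modelling answers it statistically: vary the proportions of
the component drugs systematically, fingerprint every variant by LC-MS,
measure every variant's bioactivity, and regress activity on constituent
abundance. Constituents whose abundance tracks activity across the variants
are the predicted actives.

`spectreff` implements that workflow end to end: mixture uniform design,
peak source attribution, preprocessing, PLS1 regression with leave-one-out
model selection, coefficient ranking — plus a synthetic-data generator that
lets every stage be validated against planted ground truth.

## Mixture uniform design

Proportions of `s` drugs live on the simplex, so ordinary factorial designs
do not apply. We use the good-lattice-point (GLP) construction: an integer
table `levels[i, j] = ((i·h_j − 1) mod N) + 1` built from a generating
vector `h` of integers coprime with the modulus, each column a permutation
of `1..n`. When `n` itself has too few coprimes (n = 12 has only 1, 5, 7,
11), the construction runs modulo `n + 1` over `n + 1` rows and drops the
final row, which is always the constant row. Levels are centred onto the
unit hypercube, `c = (2·level − 1)/(2n)`, and mapped to compositions by the
inverse-power transform

$$x_k = \left(1 - c_k^{1/(s-k)}\right)\prod_{j<k} c_j^{1/(s-j)}, \qquad
  x_s = \prod_{j=1}^{s-1} c_j^{1/(s-j)},$$

whose products telescope so each row sums to one exactly. Printed design
tables round to integer percent; `to_percent()` rounds half-up and does
*not* renormalise, so row sums of a printed table may be 99–101. This is
deliberate: it makes the package's output comparable digit-for-digit with
published tables, and `recover_levels()` inverts a printed table back to the
integer levels (snapping each recovered `c` to the grid, rejecting rows
farther than half a grid spacing from every grid point).

For the 12-run, six-drug case study shipped with the package, inversion of
the printed percent table yields levels that are exactly the GLP table with
generating vector (1, 3, 4, 9, 12) modulo 13 — so that vector is the
package default for this design size. Component order matters (the transform
is not symmetric in the columns), so component names are a parameter, never
hard-coded.

## Peak matching and source attribution

Peaks are matched within an ionization mode when both the retention-time and
m/z differences fall inside tolerances, default `rt_tol = 0.2` min and
`mz_tol = 0.5` Th — half a nominal mass unit, appropriate for
unit-resolution triple-quadrupole data where catalog m/z values are
integers; both are arguments everywhere. Among gated candidates the smallest
normalised distance `|Δrt|/rt_tol + |Δmz|/mz_tol` wins, assignment is
one-to-one and greedy in ascending distance, and ties break by lower
retention time then lower m/z, so matching is deterministic. Modes are never
cross-matched.

`attribute_sources()` turns each mixed-formula peak into a catalog feature
(ids `P1..Pk`, `N1..Nm` in elution order within mode) whose `source_herbs`
collects every single-drug decoction that matches it; features matching no
herb are flagged `unassigned` rather than dropped.
`assemble_intensity_matrix()` fills the samples × features matrix with the
matched intensities and writes **zero** where a feature is absent from a
sample — absence of evidence is treated as absence. That choice biases
autoscaled values for rarely detected features and is the main reason
zero-variance columns can appear downstream; they are dropped with a warning
during autoscaling.

## Preprocessing

A lower CCL17 concentration means stronger inhibition, so the response is
inverted, `y = 1/CCL17`, *before* scaling — the reciprocal-first order is
the only one supported. Both blocks are then autoscaled column-wise with the
sample (n − 1) standard deviation; the n − 1 convention is configurable in
spirit but fixed in code, since with 13 samples the difference is a constant
factor that PLS absorbs. The MTT viability helper follows the assay formula
exactly: mean absorbance of tested wells over mean absorbance of control
wells × 100 (mean-first, not averaged per-well ratios — the two differ
whenever control wells vary).

## PLS1, cross-validation, and latent-variable choice

With p ≈ 68 features and n = 13 samples, ordinary least squares is
underdetermined and collinear; partial least squares handles both. The
single-response NIPALS algorithm is closed-form per component (weight
`w = X'y/‖X'y‖`, score `t = Xw`, loadings `p = X't/t't`, `q = y't/t't`,
then deflation of both blocks), and coefficients on the scaled predictors
are `b = W(P'W)^{-1}q`. Scores are orthogonal by construction and both
cumulative variance-explained series are monotone — properties the test
suite asserts, along with exact agreement with the minimum-norm
least-squares solution at full rank.

`loo_rmsecv()` refits the scaling parameters inside every leave-one-out fold
by default (no information leakage from the held-out sample);
`rescale_folds = FALSE` mimics tools that scale once up front. Errors are
expressed in the full-data scaled-y convention so the curve is comparable
across component counts. The curve's minimum is not the whole story in this
regime — RMSECV often drifts slowly downward long after the real structure
is captured — so the default selection rule takes "the last meaningful
drop": the largest `A` whose relative improvement over the previous RMSECV
is at least `rel_tol = 0.02`. The threshold quantifies an inherently visual
judgement and is therefore both configurable and bypassable
(`components = ...` overrides selection entirely, matching practice where
the analyst picks the elbow from the plot).

## The synthetic generator

`simulate_dataset()` produces data with exactly the structure the inference
assumes, so recovery tests probe the inference rather than model mismatch:

* **Fingerprints.** Six herbs with (12, 11, 11, 11, 11, 12) compounds — 68
  catalog features, the case-study scale — with log-normal base intensities
  (median 1e5, log-sd 1, the right order for ion counts), retention times
  uniform on 2–72 min, integer m/z on 125–580. `shared_fraction` defaults to
  0 because every feature of the case-study catalog has a single source
  herb; sharing is exercised separately in the matching tests.
* **Mixing.** `X[j, c] = (Σ_h p[j,h]·I[c,h]) · exp(ε)`, `ε ~ N(0, σ_x²)`
  with σ_x = 0.2: multiplicative noise, because LC-MS intensity error scales
  with signal. Mixing is mass-proportional; co-extraction chemistry, matrix
  effects, chromatographic drift and batch effects are deliberately not
  modelled.
* **Response.** `u = α + Σ_c β_c z_c + e` on the autoscaled intensities,
  with the observed concentration `CCL17 = 1/u` — so the pipeline's
  reciprocal transform linearises the truth exactly. Defaults: 5 planted
  actives with β = +0.5 each, α = 5 (keeps `u` bounded away from zero:
  autoscaled entries of a 13-row column cannot exceed 3.33 in magnitude, and
  a positivity guard redraws the noise, at most 100 times, if `u` still
  touches 1e-4), response noise 5 % of the mean linear predictor. The
  resulting concentration scale is arbitrary — the analysis is invariant to
  it — and the generator makes no claim about pg/mL realism.

The 13 × 68 default mirrors the case-study dimensions so test behaviour
reflects the real p ≫ n regime.

## What coefficient ranking can and cannot resolve

Ranking features by signed RC (positive = promotes inhibition, since the
response is reciprocal concentration) is the method's instrument for
nominating actives, and ties break lexicographically by feature id so ranks
are reproducible. Two structural limits deserve emphasis:

* **Within-herb collinearity.** The mixing model is rank-`s`: without noise,
  every single-source feature of one herb has an *identical* autoscaled
  profile, and with σ_x = 0.2 sibling features still correlate around 0.94.
  A regression on 13 samples cannot apportion credit among ~11 near-copies;
  coefficients spread across a herb's features, and the ranking resolves the
  active *herb* far more reliably than the active *feature*. The test suite
  measures this honestly: a single planted active with a noise-free response
  is top-ranked in most but not all seeds (a near-collinear sibling
  occasionally edges it out at the cross-validation-selected model size),
  and with five planted actives the top-5 set typically captures only a
  minority of them even at the most favourable model size. Conclusions at
  single-compound resolution need orthogonal evidence (literature,
  follow-up assays on candidates), exactly as practitioners treat such
  rankings.
* **Noise-free degeneracy.** With σ_x = 0 the sibling profiles are exactly
  equal, coefficients tie exactly, and single-feature recovery is undecidable
  in principle; recovery benchmarks therefore always keep the intensity
  noise on.

## Numerical choices and degenerate inputs

Zero-variance columns are dropped (with their names recorded) rather than
erroring; an all-constant block errors. `fit_pls1` stops when the residual
covariance `X'y` is numerically zero at the first component and truncates
with a warning if deflation exhausts the response later. PLS1 NIPALS needs
no iteration, so there are no convergence tolerances to tune. Matching uses
strict `<=` tolerance gates; equal-distance candidates are ordered by
coordinates. All simulation entry points take a seed and the full chain is
deterministic under it.

## Problem sizes used by the test suite

Design checks run the full 12-run case-study table; oracle comparisons use
twenty random 10 × 20 least-squares instances and a complete 13 × 68
fold-by-fold cross-validation replay; recovery benchmarks run 25 seeds of
the default 13 × 68 generator (and 25 single-active seeds); the permutation
negative control uses 20 response permutations. These sizes keep the whole
suite under a minute while exercising the regime the method is built for.
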