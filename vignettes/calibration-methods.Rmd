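---
title: "Bayesian calibration of PCR bias in bisulfite amplicon assays"
author: "AmpliCal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian calibration of PCR bias in bisulfite amplicon assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmpliCal)
```

## The problem

Bisulfite amplicon sequencing measures methylation per CpG as the fraction of
reads carrying a cytosine after conversion. PCR amplifies the methylated and
unmethylated template with different efficiencies ("PCR bias"), so the
*apparent* methylation after amplification is a distorted, assay-specific
function of the *actual* methylation. Standard controls — mixtures of fully
methylated and unmethylated DNA at known actual methylation percentages
(AMPs), typically 0/25/50/75/100% — let one estimate that distortion as a
calibration curve and invert it on patient samples.

The classical baseline fits an independent cubic polynomial of apparent on
actual methylation for every CpG (the CPR, `fitCPR()`). With five controls
this model is saturated: five parameters per CpG against five observations,
leaving no residual degrees of freedom and very unstable out-of-sample
prediction. AmpliCal instead models all CpGs of a CpG island or DMR jointly.

## The model family

All `l * m` observations (AMP level `i`, CpG `j`) enter one mixed additive
regression on the percent scale:

```
y_ij = b0 + b1 x_ij + b2 x_ij^2 + b3 x_ij^3 + RE_ij + e_ij,   e_ij ~ N(0, s2)
```

with four nested choices of the random-effects term `RE_ij`:

* **M1** — AMP effects only: `AMP_i ~ N(0, 1/tau)`. Captures shared per-level
  deviations from the cubic trend.
* **M2** — adds crossed CpG effects `CpG_j ~ N(0, 1/upsilon)` for the
  heterogeneity across CpGs.
* **M3** — replaces the CpG effects by a latent Gaussian field `mu_j` with
  first-order random-walk dependence over genomic positions:
  `mu_j | mu_{j-1} ~ N(mu_{j-1}, rho * |p_j - p_{j-1}|)`. The closer two
  CpGs, the stronger their dependence.
* **M4** — correlated per-CpG random intercepts and slopes
  `(CpG_j, CpG*_j) ~ N2(0, Sigma^-1)`, which lets the across-CpG spread grow
  or shrink with the AMP (the typical funnel shape of PCR bias).

Identifiability requires `sum(AMP_i) = 0`, `sum(CpG_j) = 0`,
`sum(CpG*_j) = 0`; AmpliCal enforces these exactly by expressing every
effect block in an orthonormal basis of the sum-to-zero subspace rather than
by soft penalties, so posterior means of the effect vectors sum to zero by
construction. The latent field is likewise centered (the intrinsic RW1
convention), keeping the intercept identified; a literal "anchored at
position zero" variant is available via
`makeModelSpec(..., rw1FirstState = "anchored")`, where the first increment
has variance `rho * p_1` and is effectively diffuse at chromosomal
coordinates.

### Priors and their defaults

`defaultPriors()` returns the hyperparameters; all can be overridden in
`makeModelSpec()`:

| parameter | prior | default | role |
|---|---|---|---|
| `b1..b3` | Normal(0, 1e3) | variance 1e3 | non-informative trend |
| `b0` | Normal(0, 1e6) | variance 1e6 | diffuse intercept |
| `tau`, `upsilon` | Gamma(1, 0.1) | mean 10, var 100 | effect precisions |
| `rho` | precision ~ Gamma(1, 0.1) | — | RW1 variance per bp |
| `Sigma` | Wishart(r = 4, R = I2) | `E(Sigma^-1) = R/(r-3)` | intercept/slope precision |
| `s2` | InvGamma(1e-10, 0.001) | near-flat | error variance |

Two deliberate design choices here. First, an improper reciprocal prior on
the intercept is a positive-scale prior and cannot support an intercept near
zero; AmpliCal uses a diffuse normal (variance 1e6, configurable) instead.
Second, the residual-variance prior is read as a Gamma(shape, rate) on the
precision; `sigma2Parameterization = "scale"` switches the reading (both are
near-flat, so the fit is insensitive to the choice).

## Inference: blocked Gibbs sampling

Given the variance components, the model is linear-Gaussian, and all
variance components have conjugate conditionals. `fitCalibration()` therefore
alternates

1. a *joint* draw of every location parameter (polynomial coefficients and
   all effect blocks in their centered bases) from the exact Gaussian full
   conditional — one Cholesky factorization per sweep, which removes the
   random-walk behaviour that one-at-a-time updates would suffer along the
   cubic-vs-AMP-effect ridge (see below); and
2. conjugate updates: Gamma for the residual precision and for `tau`,
   `upsilon`, an inverse-Gamma update for `rho` from the RW1 increments, and
   a Wishart update for the intercept/slope precision.

The polynomial is computed internally on `x/100` with the priors transported
exactly, purely for numerical conditioning; all reported coefficients are on
the raw percent scale. Missing cells are simply excluded from the
likelihood — no data augmentation — which matches the removal-then-imputation
workflow: `imputeMissing()` predicts absent cells from the terms common to
all CpGs (posterior-mean polynomial plus AMP effect), clipped to \[0,100\].

Convergence is gated by split-Rhat on the polynomial coefficients and the
log variance components (threshold 1.05). Because leave-one-out refits run
hundreds of reduced-draw fits, the gate warns and records
`converged = FALSE` by default instead of aborting;
`engineOptions(onNonconvergence = "error")` restores the strict behaviour.
Every fit is exactly reproducible from its integer seed, and the sampler
leaves the caller's RNG state untouched.

Reported per-cell means are the additive sums of component posterior means,
clipped to \[0,100\]; clipping is applied to *reported* summaries only,
never inside the Gaussian likelihood. Predictive bands come from joint
posterior draws of the full linear predictor (plus residual draws for the
posterior predictive); the literal additive-quantile composition — summing
componentwise quantiles — is available via
`posteriorPredict(..., additive = TRUE)` but ignores posterior dependence
between components and is kept only as a fidelity switch.

### Model choice and DIC

`selectModel()` picks the minimum-DIC model, breaking ties toward the
simpler model in the order M1 < M2 < M3 < M4. The DIC uses the conditional
deviance (conditioning on the latent effects): `Dbar + pD` with
`pD = Dbar - Dhat`, `Dhat` evaluated at the posterior means of the linear
predictor and error variance. This is the variant most deployed inference
engines report for latent Gaussian models, and in simulation it recovers the
generating model reliably (the test suite checks an M4-vs-M1 contrast).

### Identifiability of the cubic trend

With five AMP levels, the cubic trend (four coefficients) plus four free
sum-to-zero AMP effects exceed the five distinct design points: only their
sum is likelihood-identified, and the posterior split between trend and
effects is governed by the priors. This is intrinsic to the model family,
not an artifact of the sampler. Two practical consequences:

* Calibration curves are unaffected — they depend on the identified sum
  (polynomial plus interpolated AMP effect).
* Credible intervals for individual coefficients are calibrated when the
  generating effects are consonant with the priors. The package's recovery
  experiments therefore draw effects from the model at prior-typical
  variance components (`tau = upsilon = 7`, near the Gamma(1, 0.1) median;
  `rho = 0.14`; `Sigma = I`, the prior mean of the effect covariance) with
  `sigma2 = 4` as moderate noise, compare `beta` against its sum-to-zero
  identified reparameterization (`identifiedTruth()`), and use the
  generator's unclipped mode so boundary truncation does not distort the
  Gaussian error at the 0% and 100% controls.

## The calibration curve and its inversion

For each CpG the forward map is

```
g_j(x) = E(beta|y)'(1, x, x^2, x^3) + eta(x) + C_j(x)
```

where `eta` is a **natural cubic spline** through the posterior means of the
AMP effects at the design AMPs (the spline type is not dictated by the
model; the natural boundary condition — zero second derivative at the end
knots — is the standard reproducible choice and is what `buildCurve()`
implements, falling back to linear interpolation with only two knots), and
`C_j` is 0 / CpG effect / latent-field value / CpG effect + slope times `x`
for M1/M2/M3/M4. The spline is evaluated inside the knot range only; since
designs span 0–100%, no extrapolation is ever needed and requests outside
the range error out.

`correctObservation()` inverts `g_j` at an observed methylation level by
bounded scalar minimization of the squared deviation on \[0,100\]
(derivative-free, tolerance 1e-6 on `x`; boundary optima are legitimate
results). Monotonicity of each curve is pre-checked on a 0.1-step grid;
non-monotone curves trigger a warning and a global grid scan before local
refinement, since uniqueness of the inverse is an empirical property of
well-behaved assays, not a theorem. The same bounded-minimization scheme
inverts the per-CpG CPR baseline (`cprCorrect()`).

## Predictive evaluation

`residualSumSquares()` is the in-sample measure. `msep()` is
refit-per-deletion leave-one-out in three scenarios: deleting one cell,
one whole CpG, or one AMP level from all CpGs. For the joint model a
deleted CpG is predicted from the terms common to all CpGs, and a deleted
AMP's random effect is interpolated (natural spline) from the remaining
effects — the model cannot borrow information about an AMP that was removed
from every CpG. For the CPR a deleted CpG is predicted from its two
flanking curves, weighted by *opposite* distance (`d_R/(d_L + d_R)` on the
left flank): weighting proportionally to distance itself would upweight the
farther flank, so the linear-interpolation reading is the only sensible
one; boundary CpGs use their single nearest flank. `cvIndex()` normalizes
MSEP against the leave-one-CpG-out per-AMP mean predictor (same
missing-cell mask in numerator and denominator) and is undefined for the
AMP-deletion scenario. Leave-one-out refits reuse one seed and a reduced
draw count (configurable through the `engine` argument), keeping the
measures deterministic and desk-scale.

## Clinical classification

`controlReferenceInterval()` pools the per-CpG corrected degrees of all
control individuals and builds `center +/- k * sd`; pooling across CpGs
(rather than per-individual means) makes the interval wide enough to
contain the controls' corrected degrees across all CpGs, which is the
interval a diagnostic plot draws. The per-individual-mean alternative is
available via `aggregate = "means"`. `k = 3` corresponds to a two-sided
normal tail of 0.0027 (`kFromAlpha()` converts any alpha).
`classifySamples()` calls loss/normal/gain from each patient's mean
corrected degree and flags patients whose per-CpG range crosses an interval
bound as `uncertain` — the borderline/mosaic presentation where a call
should be read with care.

## What the synthetic generator does and does not emulate

`simulateCalibration()` draws data forward from any of the four models on a
design (packaged Table-style assay designs via `assayDesigns()`, five-point
0/25/50/75/100 or eight-point 0/12.5/.../100 control series via
`eightPointAmpLevels()`), with seed-exact reproducibility. Effects are drawn
iid (uncentered), matching the generative model; `identifiedTruth()` maps a
realized truth to the sum-to-zero parameterization the sampler identifies.
Values are clipped to \[0,100\] by default; the default truths used in the
package keep means at least 3 residual SDs inside the bounds so that
moment checks remain valid, and `clip = FALSE` provides the exact-Gaussian
oracle mode. `simulateCohort()` pushes true methylation degrees through a
known forward curve and adds Gaussian measurement noise;
`injectOutliers()` shifts chosen cells and records the provenance.

The generator emulates percent-scale Gaussian measurement error around an
additive model. It does **not** emulate read-count (binomial) noise and its
coverage dependence, incomplete bisulfite conversion, batch effects between
sequencing runs, or mosaic cell mixtures within an individual. Passing
tests on synthetic data therefore demonstrate correctness of the inference
and correction machinery under the stated model, not robustness to those
real-data phenomena. CpG positions in the packaged designs are synthesized
evenly spaced within the printed amplicon regions (true per-CpG coordinates
are not part of the metadata), which suffices for distance-based RW1
structure but not for position-exact analyses.

## Problem sizes and numerical choices

The test-suite experiments use `l = 5`, `m = 15` grids with 2 chains of 500
post-warmup draws for recovery (40 seeds per model), 30 seeds for the DIC
contrast, 20 seeds for outlier injection, 50 seeds for cohort
classification, and reduced-draw single-chain refits (300–400 iterations)
inside leave-one-out loops; these sizes give stable rates while keeping a
full run at desk scale. Other fixed numerical choices: tie-break tolerance
0 (exact ties) in `selectModel()` unless widened by the caller; dense-grid
monotonicity step 0.1; inversion tolerance 1e-6; degenerate predictive
distributions (zero IQR) collapse the outlier fences to a point, flag any
deviation, and warn.

## Known limitations

* Percentages are modeled with unbounded Gaussian error; near 0% and 100%
  the likelihood is misspecified and only reported summaries are clipped.
* With the standard five-point design the trend/effect split is
  prior-governed (see above); interpret individual coefficients
  accordingly.
* The CPR baseline with five controls is saturated; its residual variance
  rests on a single degree of freedom per CpG, and its leave-one-out
  behaviour is correspondingly erratic — which is precisely the motivation
  for the joint model.
* Outlier fences are descriptive (quartile rule on the posterior
  predictive); flagged cells are reported, never auto-removed. Refitting
  after removal is a one-liner left to the analyst.
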