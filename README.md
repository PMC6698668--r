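# AmpliCal

Bayesian calibration of PCR bias in bisulfite amplicon methylation assays.

## The problem

Bisulfite amplicon sequencing quantifies DNA methylation per CpG, but PCR
amplifies methylated and unmethylated templates with different efficiencies
("PCR bias"): the apparent methylation after amplification is an
assay-specific distortion of the actual methylation. Laboratories estimate
the distortion by sequencing standard controls of known actual methylation
percentage (AMP; e.g. 0/25/50/75/100%) and invert the resulting calibration
curve on patient samples. AmpliCal is for analysts of targeted methylation
panels — imprinting DMRs, CpG islands, clinical diagnostic assays — who need
calibrated, per-CpG corrections with honest uncertainty, outlier screening
of their control experiments, and loss/gain-of-methylation calls for
patients against a healthy-control reference.

## The model

Instead of fitting an independent cubic per CpG (the classical cubic
polynomial regression, CPR — saturated with five controls), AmpliCal models
all CpGs of a region jointly with a mixed additive regression on the
percent scale:

    y_ij = b0 + b1 x_ij + b2 x_ij^2 + b3 x_ij^3 + RE_ij + e_ij,  e_ij ~ N(0, s2)

with four nested random-effects structures: AMP effects only (M1), crossed
AMP + CpG effects (M2), an RW1 latent Gaussian field over CpG positions
(M3), and correlated per-CpG random intercepts and slopes (M4), all under
sum-to-zero identifiability constraints. Fitting is fully Bayesian via a
blocked Gibbs sampler (joint Gaussian location draw + conjugate variance
updates); the model with the lowest DIC is selected. The per-CpG
calibration curve

    g_j(x) = E(beta|y)'(1,x,x^2,x^3) + eta(x) + C_j(x)

(`eta` a natural cubic spline through the posterior-mean AMP effects,
`C_j` the model-specific per-CpG offset) is inverted by bounded scalar
minimization to obtain corrected methylation degrees; controls define a
`center ± k·SD` reference interval (k = 3 ⇒ two-sided alpha 0.0027) for
loss/normal/gain classification. See `vignettes/calibration-methods.Rmd`
for the full account.

## Worked example

```r
library(AmpliCal)

design <- assayDesigns()[["KCNQ1OT1"]]     # chr11:2721402-2721616, 17 CpGs
truth  <- truthParams(beta = c(8, 1.1, -0.006, 2e-5), sigma2 = 2,
                      tau = 0.25, upsilon = 0.1)
sim <- simulateCalibration(design, truth, "M2", seed = 11)

fits <- lapply(setNames(nm = c("M1", "M2", "M3", "M4")), function(m)
  fitCalibration(sim$data, makeModelSpec(m),
                 engineOptions(chains = 2, iter = 750, warmup = 350, seed = 7)))
round(sapply(fits, dic), 2)
#>     M1     M2     M3     M4
#> 397.52 319.79 321.12 353.80
selectModel(sapply(fits, dic))
#> [1] "M2"
```

DIC picks the generating model: the crossed-effects model beats both the
AMP-only model (which ignores CpG heterogeneity) and the heavier M4 (whose
extra slopes are not supported by these data). The posterior of the trend:

```r
fit <- fits[["M2"]]
round(fit@summary$beta, 4)
#>          mean    q2.5     q25     q50     q75   q97.5
#> beta0  5.9764  4.8188  5.6205  5.9710  6.3350  7.1728
#> beta1  1.2144  1.0744  1.1763  1.2153  1.2515  1.3410
#> beta2 -0.0110 -0.0142 -0.0119 -0.0110 -0.0100 -0.0076
#> beta3  0.0001  0.0000  0.0001  0.0001  0.0001  0.0001
```

Build the calibration curves, correct an observation, and push a small
cohort through the pipeline:

```r
curve <- buildCurve(fit)
curve
#> CalibrationCurve (M2): 17 CpGs, spline knots at 0, 25, 50, 75, 100
#>   monotone on [0,100]: 17 of 17 CpGs

correctObservation(curve, 5, 62)   # observed 62% at CpG 5
#> [1] 79.62325

cohort <- simulateCohort(curve, matrix(rep(c(30, 50, 80), 17), 3, 17),
                         c("control", "control", "case"), noiseSd = 1, seed = 2)
round(correctedMeans(correctSamples(curve, cohort$samples)), 2)
#>    s1    s2    s3
#> 29.56 49.91 80.81
```

An observed 62% maps back to a corrected degree of 79.6% — the assay
under-reports high methylation — and the cohort's true degrees (30/50/80)
are recovered from biased, noisy observations to within a percentage point.
`flagOutliers(fit)` screens the control experiment with quartile fences on
the posterior predictive, `msep()`/`cvIndex()` quantify leave-one-out
predictive performance against the CPR baseline (`fitCPR()`), and
`controlReferenceInterval()` + `classifySamples()` make the clinical calls.

A command-line wrapper with subcommands `simulate`, `fit`, `calibrate`,
`correct`, `evaluate` and `classify` is installed at
`inst/scripts/amplical.R` (see `?ampliCalRun`).

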