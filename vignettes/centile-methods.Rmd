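---
title: "Constructing gestational-age-related centile charts with centilefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing gestational-age-related centile charts with centilefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centilefit)
```

## The problem

A growth reference chart summarizes, for every gestational age (GA), the
distribution of a body measurement in a reference population by a handful
of centile curves. Statistically this is density estimation under strong
structural constraints: the age-conditional distribution must change
smoothly with GA, the outer centiles must be well calibrated (about 3% of
reference data below the 3rd centile at every age), centiles must never
cross, and the model must invert cleanly so an individual measurement can
be turned into a Z-score. `centilefit` implements the three families of
methods that dominate this field — fractional-polynomial (FP) mean–SD
regression, LMS-type distributional models, and multilevel models for
longitudinal designs — along with the diagnostics used to choose between
them.

## Fractional polynomials

All smooth age curves in the package are built from fractional polynomials:
linear models in powers of GA drawn from the restricted set
{−2, −1, −0.5, 0, 0.5, 1, 2, 3}, with power 0 meaning log(GA) and a power
repeated r times contributing x^p·log(x)^0..r−1. This family is preferred
over ordinary polynomials in prenatal growth work because it reaches many
more curve shapes (including asymptote-like behaviour) with very few terms.
`fit_fp()` performs the exhaustive least-squares search over all canonical
power tuples: 8 models at degree 1, 36 at degree 2, 120 at degree 3. (Note
that the count of distinct FP2 models is sometimes quoted as 32; direct
enumeration of non-decreasing pairs with repetition over an 8-element set
gives C(8,2) + 8 = 36, and the package enumerates all 36.) Ties in residual
deviance are broken toward the lexicographically smallest power tuple so
fits are reproducible; rank-deficient candidate bases are skipped with a
warning rather than aborting the search.

GA is used in natural weeks without rescaling, because published chart
equations in this field (including the fetal head circumference standard
bundled in the package) are stated in raw GA weeks.

## The mean–SD method

`fit_mean_sd()` assumes conditional normality: the mean is an FP of GA
(degree 2 by default), and the SD is estimated by regressing the absolute
residuals on GA as a second FP (degree 1 by default, configurable to 3)
and multiplying the fitted curve by √(π/2), the half-normal correction.
Optionally one — exactly one — reweighting pass refits the mean with
weights 1/σ̂²; the effect is usually negligible, which is why iteration to
convergence is not offered. Skewed measurements can be handled on a log or
shifted-log scale (`log(y + k)`), with centiles back-transformed.

Numerical choices worth knowing:

* The fitted SD is checked on a 201-point grid over the observed GA range;
  it must not be negative beyond a small numerical tolerance. A SD that is
  *numerically zero* (noiseless data) is allowed and simply collapses all
  centiles onto the mean, which is the sensible degenerate limit.
* Centile and Z-score evaluation outside the fitted GA range is permitted
  — published charts are typically tabulated on round-week grids that can
  extend slightly beyond the data — but the result carries an
  `"extrapolated"` attribute and a warning.

## Distribution families and LMS-type models

Seven families are available: NO, PE, BCCG, BCT, BCPE, SEP3 and ST3, in
the parameterizations conventional in the GAMLSS literature (BCCG: mu =
median, sigma = coefficient of variation, nu = Box-Cox power; BCT/BCPE add
a kurtosis parameter tau; SEP3/ST3 are two-piece skew families). The
densities, CDFs, quantile functions and random generators are implemented
directly in the package and are validated in the test suite against
independent numeric oracles: numerical integration of each density,
quantile/CDF round trips, and closed-form reductions (PE(ν=2) = normal,
SEP3(ν=1, τ=2) = normal, ST3(ν=1) = t, BCPE(τ=2) = BCCG, BCT → BCCG as
τ → ∞). The Box-Cox families use the standard convention of truncating the
transformed variable to the region giving y > 0 and renormalizing. The
closed-form LMS equations (`lms_centile()`, `lms_sds()`) switch to their
log-form branch when |L| < 1e-8; the branches agree to better than 1e-6
relative at the switch.

`fit_centile_model()` fits a distributional centile model in which each
parameter is a smooth function of GA:

* curve kinds: `constant` (edf 1), `fp` (fixed powers), or `pspline` — a
  cubic B-spline with equally spaced knots and a second-order
  divided-difference penalty at the Greville abscissae, so the penalty null
  space is exactly the straight lines and edf → 2 recovers a linear curve.
* the smoothing parameter λ is solved inwardly (by `uniroot` on
  tr[(BᵀB + λP)⁻¹BᵀB]) to hit the *requested* edf, which may be fractional
  (e.g. 3.6); automatic smoothing selection is deliberately out of scope.
  The edf is computed on the unweighted basis, a standard approximation.
* links: sigma and tau are fitted on the log scale; the Box-Cox power nu on
  the identity; the positive skew/power nu of PE, SEP3 and ST3 also on the
  log scale. Keeping every positivity-constrained parameter on a log link
  avoids constrained optimization — this is why the package extends the
  log link to nu for those three families.
* optimization: cyclic updates — each parameter's coefficient vector is
  refitted by BFGS holding the others fixed — until the penalized deviance
  changes by less than 1e-4, with a cap of 500 cycles (both configurable).
  The cyclic scheme is a design choice validated by parameter recovery on
  simulated data, not a claim about any particular historical
  implementation. Initialization is least squares for mu, the residual
  SD (or CV) for sigma, and normal-like values for the shape parameters.

`fit_report()` accompanies every fit with the global deviance (−2 log L),
total edf, AIC = GAIC(2), BIC = GAIC(log n), and the empirical percentage
of training records below the 3rd and above the 97th fitted centiles.
`stepwise_class_selection()` implements add-up stepwise search: the best
model inside each of the 2-, 3- and 4-parameter classes is found by
GAIC(k), and a more complex class is adopted only when it strictly improves
on the incumbent (by more than a configurable margin, default 0). The full
ranked table is returned because chart selection in practice also weighs
non-statistical criteria (fit at the extremes, a common family across
sexes) that a single number cannot capture.

## Multilevel models for longitudinal data

For designs with repeated visits and triplicate measurements,
`fit_multilevel()` fits (via `lme4`, by full maximum likelihood so that
deviances are comparable across fixed-effect structures):

* `ri2` — two-level random intercept, on per-visit collapsed values;
* `ris2` — two-level random intercept + GA-slope;
* `ris3` — three-level: subject intercept + slope, a visit-level
  intercept, and the replicate-level residual, on the full data.

`collapse_triplicates()` collapses replicates by mean (default), median
(more robust to contamination) or seeded random selection. The random
slope multiplies raw GA by default; centering is available and only
reparameterizes the intercept/slope covariance. Variance estimates pinned
at zero are reported with a `boundary` flag rather than as errors.

Centiles from a multilevel fit need a marginal SD: `marginal_sd_curve()`
assembles the total variance at each GA from the components
(σ²_int + 2·cov·t + σ²_slope·t² + σ²_visit + σ²_resid, as present in the
model), takes the square root on a grid, and smooths it as an FP (degree 3
by default, matching how published fetal SD equations are typically
stated). Whether published SD equations were historically derived from
model-implied or empirical residual SDs is usually not documented; this
package takes the model-implied route and states it.

The package ships the published FHC standard equations
(`published_fhc_chart()`): mean −28.2849 + 1.69267·GA² − 0.397485·GA²·log GA
and SD 1.98735 + 0.0136772·GA³ − 0.00726264·GA³·log GA +
0.000976253·GA³·(log GA)², in mm over 14–42 weeks, natural logs. They serve
both as an evaluable chart and as the truth for the longitudinal generator.

## Synthetic data generators

`gen_newborn()` emulates a cross-sectional newborn study: completed weeks
33–42 are drawn from the per-week delivery counts of the emulated design
(heaped at 39–40 weeks, under 1% before 34 weeks), the within-week
position is uniform (only completed-week counts are ever reported in such
tables), and the measurement is drawn from any supported family with
user-supplied true parameter curves. The default truth is a normal
birthweight-like model (mean ≈ 3.4 kg at 40 weeks, SD growing with GA) —
realistic in scale, and deliberately simple so recovery tests have an
unambiguous target.

`gen_fetal()` emulates the longitudinal design: 4233 subjects by default,
first visit in week 14, subsequent visits every 5 ± 1 weeks (uniform
jitter) truncated at 42 weeks, visit counts drawn from the observed 1–6
distribution (93% attend ≥ 4), subject-level random intercepts and slopes,
visit-level noise, and triplicates with independent replicate error masked
completely at random at rate 117/60090. The default variance components
(σ²_int = 47.3, σ²_slope = 0.2018, cov = −2.455, σ²_visit = 4,
replicate SD = 3 mm) were chosen once, before any testing, by solving a
3 × 3 linear system so that the implied total SD matches the published FHC
SD equation at 14, 28 and 42 weeks — making the published standard double
as the generator truth. The replicate SD of 3 mm is a realistic ultrasound
triplicate error; no published value exists for it.

What the generators do *not* emulate: site/country heterogeneity (the
design's third level of context), GA-estimation error, non-random
missingness, and digit preference in measurements. Passing recovery tests
on these generators therefore demonstrates correctness of the estimators
under the stated model, not robustness to all features of real data.

## Diagnostics

`worm_data()` produces detrended Q-Q data per GA group: equal-count
quantile bins (default 9; the literature rarely states a grouping rule, so
equal counts keep per-group precision comparable), deviations = ordered
Z-scores minus normal quantiles at Blom plotting positions, and a plain
least-squares cubic summarizing each worm's shape (a penalized-spline
smoother is sometimes used instead; the cubic is simpler and its cubic
coefficient is a direct kurtosis signal). Groups under 10 observations are
merged with a neighbour. `coverage()` reports tail coverage with exact
binomial intervals; `qq_data()` and `residual_age_data()` provide the
standard single-panel diagnostics; `comparison_table()` ranks fit reports,
applying any display offset only at presentation.

## Problem sizes and determinism

The test suite and the acceptance script fit at n = 400–10 000 records and
250–1000 subjects, which this methodology handles in seconds per fit while
leaving Monte-Carlo noise well below the tolerances asserted. Every
stochastic step is seeded: generators take an explicit seed, and
`family_random()`/`collapse_triplicates(method = "random")` accept one.
All fits are deterministic given data and specification.

## Known limitations

* Automatic smoothing-parameter selection (GCV/ML) and the closed-test FP
  power-selection procedure are not implemented; smoothness is specified
  by target edf and FP degree.
* The cyclic penalized-likelihood fitter can be slow for 4-parameter
  families with several spline curves, and like all such schemes can stop
  at a local optimum for poorly identified shape parameters.
* Nonparametric quantile regression, visual predictive checks, NPDE,
  brokenstick and linear-spline approaches are out of scope.
* Centile crossing is checked (and refused) at chart-writing time rather
  than being structurally impossible for every family/curve combination.
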