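# centilefit

Construction of gestational-age-related reference and standard centile
charts for fetal and newborn anthropometry.

Clinicians judge fetal and newborn size against charts showing a few
selected centiles (typically the 3rd, 50th and 97th) of a measurement —
birthweight, fetal head circumference (FHC), femur length — as a smooth
function of gestational age (GA). Good charts must change smoothly with
age, fit the outer centiles well, never cross, convert measurements to
Z-scores in closed form, and come from models no more complex than the data
demand. `centilefit` implements the statistical toolkit used to build such
charts from both cross-sectional data (one measurement per newborn) and
longitudinal ultrasound data (repeated visits with triplicate
measurements), together with the diagnostics used to choose among models.

## Methods

**Fractional-polynomial (FP) mean–SD method.** At each GA the measurement
is assumed normal with smoothly varying mean and SD. The mean is a
fractional polynomial of GA — powers chosen from
{−2, −1, −0.5, 0, 0.5, 1, 2, 3}, where power 0 denotes log(x) and repeated
powers contribute log-multiplied terms — selected by exhaustive least-squares
search (8 FP1, 36 FP2, 120 FP3 candidate models). The age-specific SD comes
from regressing the absolute residuals |r| on GA and scaling by √(π/2),
since under normality E|r| = σ√(2/π). Centiles follow as

    C₁₀₀α(t) = μ(t) + z_α · σ(t),       z₀.₉₇ ≈ 1.88

**LMS, LMST, LMSP methods.** For skewed and/or kurtotic data, the
age-conditional distribution is modelled directly: the LMS method uses the
Box-Cox Cole–Green (BCCG) distribution with three age-varying curves — the
Box-Cox power L(t), median M(t) and coefficient of variation S(t) — giving

    C₁₀₀α(t) = M(t)·(1 + L(t)·S(t)·z_α)^{1/L(t)}   (L ≠ 0)
    C₁₀₀α(t) = M(t)·exp(S(t)·z_α)                  (L = 0)

with the SDS (Z-score) as exact inverse. LMST and LMSP replace BCCG by the
Box-Cox t (BCT) and Box-Cox power exponential (BCPE) distributions to model
kurtosis as well; the NO, PE, SEP3 and ST3 families are also available.
Parameter curves are constants, fractional polynomials, or penalized cubic
splines smoothed to a target effective degrees of freedom (edf), fitted by
maximum penalized likelihood with cyclic parameter updates. Models are
compared by global deviance, AIC, BIC, the generalized AIC with penalty k
per df, worm plots, Q-Q plots and empirical centile coverage (about 3% of
the data should fall below the fitted 3rd centile), with an add-up stepwise
search across the 2-, 3- and 4-parameter model classes.

**Multilevel models for longitudinal data.** Repeated FHC-style data
(triplicate measurements within visits within subjects) are fitted by
linear mixed models with an FP2 fixed mean in GA: a two-level random
intercept model on triplicate means, a two-level random intercept + slope
model, or a three-level random intercept + slope model on all replicates.
The marginal SD used for centiles is assembled from the variance components
and smoothed as a third-order FP. The published international FHC standard
equations (mean FP2 with powers (2, 2); SD FP3 with powers (3, 3, 3), in mm)
are built in for evaluation and comparison.

Synthetic generators emulate both study designs — a newborn cross-sectional
sample with the characteristic heaped GA distribution (mode at 39–40 weeks,
very few deliveries before 34 weeks) and a longitudinal fetal cohort
(visits every 5 ± 1 weeks from week 14, 1–6 visits per subject with 93%
attending at least four, triplicates with realistic replicate error and
missingness) — so every fitting route can be exercised and validated by
parameter recovery without any external data.

## Worked example

```r
library(centilefit)

sim   <- gen_newborn(crosssec_config(n = 5000, sex = "M", seed = 42))
model <- fit_mean_sd(sim$records)
model
#> Fractional-polynomial mean-SD centile model
#>   n = 5000, GA range [33.07, 42.98] weeks, transform = none
#>   mean: FP2 powers (3, 3)
#>   SD:   sqrt(pi/2) x FP1 powers (-2) of |residual|

round(chart_table(model, c(3, 50, 97), 34:42), 1)
#>   ga_weeks     p3    p50    p97
#> 1       34 1447.9 2091.9 2735.9
#> 2       35 1663.9 2328.7 2993.5
#> 3       36 1876.0 2560.0 3243.9
#> 4       37 2082.9 2784.4 3485.9
#> 5       38 2283.0 3000.7 3718.4
#> 6       39 2474.9 3207.6 3940.2
#> 7       40 2657.1 3403.7 4150.2
#> 8       41 2828.2 3587.6 4347.0
#> 9       42 2986.6 3758.0 4529.4

normal_zscore(model, 36.5, 2500)   # a 2500 g boy at 36.5 weeks
#> -0.47
published_fhc(40, 50)              # FHC standard, 50th centile at 40 weeks
#> 333.9 mm
```

The chart rows are the fitted 3rd/50th/97th birthweight centiles (grams) by
completed week; the Z-score places an individual newborn on the fitted
age-conditional distribution (−0.47 = just below the median for age); the
FHC value evaluates the published closed-form standard.

A command-line wrapper with `simulate`, `fit-crosssec`, `fit-long`,
`centiles`, `zscore` and `diagnose` subcommands is installed at
`inst/cli/centilefit` (see `?cli`).

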