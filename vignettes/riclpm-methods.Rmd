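---
title: "Modelling the co-development of two repeatedly measured constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the co-development of two repeatedly measured constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riclpm)
```

## The scientific problem

Longitudinal cohort studies often measure a mental-health construct (for
example a 0–26 depressive-symptom questionnaire total) and a physical-health
marker (for example fat mass index, kg/m²) repeatedly from childhood into
adulthood, and ask whether the two *co-develop*: does a child who gains
adiposity beyond their own usual level go on to report more depressive
symptoms than usual, and vice versa? Answering this requires separating two
very different sources of association:

* **between-person** stability — some people simply run high on both
  constructs throughout the study, for reasons (sex, genetics, family
  environment) that are largely time-invariant;
* **within-person** dynamics — wave-to-wave fluctuations around a person's
  own level, whose lagged relations carry the Granger-style directional
  information.

The lag-1 **random-intercept cross-lagged panel model (RI-CLPM)** makes this
separation explicit. Each observed variable \(y_{c,t}\) (construct *c*, wave
*t*) is decomposed as

\[ y_{c,t} = \mu_{c,t} + \eta_c + w_{c,t}, \]

where \(\eta = (\eta_1, \eta_2)'\) are random intercepts with free 2×2
covariance \(\Psi\) (loading 1 on every wave of their construct), and the
within-person components follow a lag-1 vector autoregression

\[ w_{t+1} = B_t\, w_t + \varepsilon_{t+1}, \qquad
   \varepsilon_{t+1} \sim N(0, \Theta_{t+1}). \]

The diagonal of \(B_t\) holds the autoregressive (AR) paths — the
persistence of each construct — and the off-diagonal holds the cross-lagged
(CL) paths. Wave-specific residual covariances in \(\Theta_t\) absorb shocks
that move both constructs at once. Loadings are fixed to 1 and
measurement-error variances to 0; those are structural constants, not
parameters. With \(T\) waves and saturated means the model has
\(3 + 3 + 4(T-1) + 3(T-1) + 2T\) free parameters — 53 at \(T = 6\), hence
\(\chi^2\) degrees of freedom \(12\cdot15/2 - 53 = 37\).

All lagged coefficients and residual covariances are wave-specific (freely
varying), because uneven assessment schedules make a time-constant dynamic
implausible a priori; equality constraints can be imposed by comparing
variants, but are not the default.

## Estimation

No structural-equation machinery is borrowed: the likelihood, its
optimisation and all inference are implemented in this package.

**FIML over missingness patterns.** Attrition in long cohorts is heavy
(here, 15–54% per wave) and plausibly related to earlier observations, so
the model is estimated by full-information maximum likelihood: each
participant contributes the Gaussian log-density of their *observed*
sub-vector under the corresponding sub-mean and sub-covariance of the
implied moments. Rows are grouped by missingness pattern and each pattern
enters through its sufficient statistics (count, sub-mean, sub-scatter), so
one likelihood evaluation costs O(number of patterns) regardless of the
sample size.

**Gradient and optimiser.** The score with respect to the implied mean and
covariance is analytic
(\(\partial\ell/\partial\Sigma = \tfrac{n}{2}(\Sigma^{-1}(S + dd')\Sigma^{-1}
- \Sigma^{-1})\) per pattern); the Jacobian of the implied moments with
respect to the free parameters is obtained by central differences on the
cheap, data-free moment map (the saturated-mean block is handled exactly).
Covariance blocks are parameterised by Cholesky factors with log-diagonals,
keeping the optimiser (BFGS, base R `optim`) unconstrained; diagonals are
floored at \(e^{-30}\) so the intercept or slope covariance may sit on the
zero-variance boundary, which is then flagged on the fit. Convergence
requires a relative log-likelihood change below 1e-9 and a per-observation
gradient sup-norm below 1e-5; by default three additional optimisations from
perturbed starting values guard against local optima (replicate simulation
loops in the tests and the acceptance script use a single moment-based
start, which was never observed to land elsewhere in multi-start probes).
Starting values come from observed means, the halved between-person
covariance of person means, a residual variance split, and lag-1
regressions on pairwise-complete covariances.

**Standardization and inference.** A lagged coefficient \(b\) from
\(A_t\) to \(B_{t+1}\) is standardized as
\(\beta = b\,\mathrm{sd}(A_t)/\mathrm{sd}(B_{t+1})\) using the
model-implied within-component standard deviations; residual covariances
become correlations and the intercept covariance becomes the correlation
*r*. Standard errors are Huber–White sandwich estimates
\(A^{-1}BA^{-1}/n\) (mean per-row Hessian and mean outer product of per-row
scores), propagated to standardized quantities by the delta method (central
differences, step 1e-6); the conventional observed-information alternative
is available by flag and agrees within a few percent on correctly specified
data. Intervals are estimate ± 1.96·SE at the default 95% level.

**Saturated and baseline models.** The saturated model (free mean vector and
covariance) is fitted by an EM algorithm over missingness patterns — closed
form with complete data; the independence baseline separates into
per-variable univariate problems and is closed form always (baseline df
\(= p(p+3)/2 - 2p = 66\) at \(T=6\)). These feed the likelihood-ratio
\(\chi^2\), RMSEA (interval by inverting the noncentral \(\chi^2\) in its
noncentrality parameter; 95% coverage by default, 90% available), CFI, TLI
(clamped at 1 by default) and SRMR (root mean square of correlation-metric
covariance residuals over the lower triangle including the diagonal, means
excluded; under missingness the "sample" moments are the saturated FIML
estimates, keeping SRMR well defined). Adequacy flags implement
RMSEA ≤ 0.05, CFI ≥ 0.95, TLI ≥ 0.95, SRMR < 0.08, with the strict
inequality for SRMR honoured exactly.

## Preprocessing

The cleaning pipeline runs in a fixed order chosen so that each step
protects the next: extreme-outlier masking (values beyond 5 interquartile
ranges outside the quartiles are set to missing; quartiles by linear
interpolation between order statistics, R's `type = 7`; values exactly at a
fence are kept) → variance-stabilising transform (square root for the
bounded, right-skewed symptom score; natural log for the positive marker) →
min–max normalization to [0, 1]. Masking precedes the transform so a stray
negative value can never reach the log. Normalization bounds are computed
from the analysis sample *after* masking and transformation (the
alternative ordering is expressible by composing the exported primitives)
and every bound is retained in a normalization record, making the map
invertible back to the raw scale.

### A caution about per-variable min–max normalization

Normalizing each construct–wave variable by its own observed minimum and
maximum is *not* an invariance of the unit-loading RI-CLPM. The model class
is closed under one affine map per construct (the intercept loads 1 on
every wave), but per-wave bounds are extreme order statistics that vary
from wave to wave, so they rescale the waves unequally and perturb the
model structure. In simulation this shifts long-lag autoregressive
estimates upward by a few hundredths at realistic sample sizes, even though
every fit converges cleanly. `preprocess_panel()` therefore exposes
`normalize = "per_variable"` (the conventional published procedure, the
default) and `normalize = "per_construct"` (shared bounds across waves,
structure-preserving). Simulation studies that compare estimates against
generating values should use the per-construct option; analyses of real
data may prefer the conventional default for comparability, accepting the
small distortion. Standardized estimates are exactly invariant (to
optimizer tolerance, ~1e-6) under any common-scale-per-construct affine
map, and this is verified in the test suite.

## The synthetic-data generator

Because the motivating cohort data are access-restricted, the package
carries a generator that emulates the study's statistical structure, and
all tests run against it:

* six waves per construct at the uneven median ages 10.6, 12.8, 13.8, 16.6,
  17.8, 23.8 years (symptoms) and 9.8, 11.8, 13.8, 15.4, 17.8, 24.5 years
  (marker);
* generating dynamics calibrated so that the *standardized* AR/CL paths,
  wave-specific residual correlations and the intercept correlation
  (r = 0.11) equal the published reference estimates
  (`reference_estimates()`); within-person variances are held at a constant
  scale per construct, so the generating coefficient matrices coincide with
  their standardized values;
* intercept variances (0.20 and 0.08 on the transformed scale, within-person
  scales 0.775 and 0.35) sized to give modest trait stability for symptoms
  and high overall stability for adiposity once the strong AR paths are
  accounted for; wave means follow the published medians (3,3,4,4,5,5 raw
  symptom points; 3.8–7.2 kg/m²);
* raw-scale links that exercise both preprocessing branches: symptom scores
  are squared (sign-preserving), rounded and clamped to the integer range
  0–26 — emulating the instrument's coarseness — and the marker is
  exponentiated to a right-skewed positive scale;
* per-wave missingness rising from 15% to 54% (symptoms) and 24–53%
  (marker), by default MAR: the missingness log-odds at wave *t* are linear
  (slope 0.5 per SD) in the participant's wave *t−1* value of the same
  construct, with wave-1 MCAR and intercepts calibrated by root-finding so
  marginal rates match their targets exactly.

A single seed governs all draws in a documented order (intercepts, wave-1
components, innovations wave by wave, then missingness uniforms construct by
construct), so fixtures are byte-reproducible. A debug channel
(`keep_latent = TRUE`) exposes the latent intercepts and within-components
for oracle tests; it is never written to CSV fixtures.

What the generator does *not* emulate: item-level questionnaire responses
(only totals), non-Gaussian within-person dynamics, time-varying
confounding, and informative missingness beyond the previous-wave MAR
mechanism (when the conditioning value is itself missing the mechanism is
technically slightly MNAR). Passing tests therefore demonstrate correctness
of the estimator and pipeline under the assumed data-generating structure,
not robustness of the substantive findings to violations of it. Two small
deliberate distortions remain even in-class: integer rounding of the
symptom score leaves a residual upward bias of ~0.015 on its AR paths, and
per-variable normalization adds the distortion discussed above when used.

## The ALT-SR variant

The autoregressive latent trajectory model with structured residuals adds
per-construct latent linear slopes — loadings fixed at years since that
construct's first wave (0, 2.2, 3.2, 6.0, 7.2, 13.2 for symptoms) — with a
free 4×4 covariance of intercepts and slopes, and keeps the AR/CL dynamics
on the residuals. One design decision needed making: with saturated
occasion means, free slope *means* are not identified (per construct, six
occasion means plus one slope mean map onto six observed means), so slope
means are fixed to 0 and the growth in means is absorbed by the saturated
mean structure; the ALT-SR here adds exactly 7 free covariance parameters
(df = 30 at T = 6). Fitted to data generated by the RI-CLPM, the slope
variances shrink to the boundary, correctly recovering the nested model —
and the boundary is flagged on the fit object.

## Numerical choices and degenerate inputs

* Quartile estimator: linear interpolation (`type = 7`); fences depend on
  it, so it is logged.
* Constant series cannot be min–max normalized (zero denominator) and raise
  an error; all-missing series are returned from masking unchanged, with a
  warning.
* A likelihood evaluation at a numerically singular implied sub-covariance
  returns a large negative sentinel rather than NaN, which BFGS treats as a
  rejected step.
* Singular sandwich "bread" falls back to an eigenvalue pseudo-inverse with
  a warning.
* Two-wave panels abort early with an identification error (17 parameters
  versus 14 moments); three waves is the minimum (df = 1).
* TLI may exceed 1 and is clamped by default (configurable); CFI is floored
  at 0 when the model fits worse than the baseline.
* Display rounding is half-away-from-zero (0.075 → 0.08), matching the
  conventions of published tables; CSV outputs keep full precision.

## Problem sizes used in the automated checks

The test suite and the acceptance script exercise: single fits at n = 5,000
(complete and with the default missingness), 100-replicate bias checks and
200-replicate \(\chi^2\)-calibration runs at n = 2,000, Monte-Carlo moment
checks at n = 100,000 draws, and oracle comparisons on 50–120-row panels.
These sizes were chosen so each estimate's Monte-Carlo error is several
times smaller than the tolerance it is checked against.

## Known limitations

* Exactly two constructs per fit; lag-1 dynamics only; no categorical
  indicators or free loadings — this is a purpose-built co-development
  model, not a general SEM.
* The \(\chi^2\) is the plain likelihood-ratio statistic; no
  Satorra–Bentler-type scaling is applied (robustness enters through the
  sandwich standard errors, not the fit statistic).
* No imputation: FIML is the missing-data strategy, valid under MAR.
* The published per-variable normalization is reproduced faithfully but, as
  documented above, is not exactly structure-preserving; estimates from the
  two normalization modes differ by a few hundredths on long-lag paths.
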