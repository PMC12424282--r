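---
title: "Methods: models, defaults and design choices in thermofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in thermofate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofate)
```

This vignette is the package's own account of the science it implements:
the statistical models and their assumptions, the tunable parameters that
matter, what the synthetic-data generators do and do not emulate, and the
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The measurement chain

A free-ranging heliothermic lizard carries a transmitter package that
logs *surface* temperature (the logger sits against the skin, not in the
body cavity) and two-axis acceleration, while copper physical models in
the surrounding microhabitats log operative environmental temperature
hourly. Laboratory thermal-gradient trials on the same species provide
(i) the preferred body-temperature range and (ii) paired
surface/internal readings for calibration. Daily telemetry gives each
animal's fate. The package turns these streams into four families of
quantities: predicted body temperature, thermoregulation indices,
activity and performance curves, and survival estimates.

Timestamps are taken as recorded (no timezone conversion), and all daily
analyses use the half-open window [05:00, 21:00) — the diel activity
period. The right endpoint is excluded by convention; a record at
exactly 21:00 belongs to the excluded night block. Seasons follow the
Southern-Hemisphere meteorological calendar (September–November =
spring, and so on), assigned by calendar month.

## 2. Calibration and the preferred range

`fit_surface_calibration()` is ordinary least squares of internal body
temperature on surface temperature, pooled over individuals. A single
pooled model is the default because calibration data sets of this kind
are large (thousands of pairs spanning the full gradient) and the
relation is expected to be a property of the logger placement rather
than the animal; per-individual fits can be made by subsetting the pairs
upstream. Deming or orthogonal regression is deliberately not offered:
the goal is prediction of body from surface temperature, for which OLS
is the right conditional model.

`estimate_tset()` discards the first `acclimation_h` hours (default 12)
of each gradient trial, takes the 25th and 75th percentiles of the
remaining readings per individual, and averages the per-individual
bounds within sex. Percentiles use linear interpolation between order
statistics (`quantile` type 7, the default in mainstream numerical
stacks) — the convention matters at gradient sample sizes and is pinned
by an explicit sort-based oracle in the tests. A constant trace gives a
degenerate (zero-width) range and is excluded with a warning rather than
silently producing `lower == upper`.

`paired_bias()` reports mean(surface − body) with its SE and paired *t*;
the sign convention makes a positive bias mean "surface overestimates
body". When all differences are identical the SE is zero and *t* is
reported as `NA` rather than ±∞.

## 3. Thermoregulation indices

For a temperature *T* and preferred range [*L*, *U*], the deviation is 0
inside the range and the distance to the nearer bound outside it.
`hourly_db()` averages per-reading deviations of predicted body
temperature within each clock hour; `hourly_de()` computes each copper
model's deviation first and then averages across models within the hour,
so a habitat with one favourable and one hostile microhabitat scores the
mean of the two rather than the deviation of the mean. Both use the same
sex-specific range so the ratio below is coherent.

The effectiveness of thermoregulation is

$$E = 1 - \bar{d_b} / \bar{d_e}.$$

`seasonal_indices()` restricts both hourly series to hours where both
exist, averages each within a season, and forms one *E* per
individual-season from those means. This **ratio-of-means** is the
default because the alternative — averaging hourly ratios — is unstable
whenever an hour's $d_e$ approaches zero (a benign hour makes the hourly
ratio explode); `method = "mean_of_ratios"` is available for comparison.
When the seasonal mean $d_e$ is exactly zero the habitat never left the
preferred range and *E* is undefined; it is returned as `NA` with a
flag, never as ±∞. *E* ≤ 1 always, with equality exactly when
$\bar{d_b} = 0$; *E* can be negative when an animal avoids its preferred
range.

## 4. Activity

Acceleration is reduced to per-minute means of the resultant
$\sqrt{x^2 + y^2}$, computed after an affine per-axis raw-count
conversion whose default is the identity (the manufacturer's conversion
is device-specific and not published; if raw counts are supplied, set
`scale`/`offset` accordingly). Minutes are calendar-aligned (floored),
not rolling.

Movement is "any change in acceleration from the previous value",
assessed on the 1-minute means. Taken literally, *any* change would flag
floating-point jitter, so the change threshold `epsilon` is explicit,
default $10^{-6}$ m/s² — far below any physical signal, so it only
suppresses exact-representation noise. Activity is then minutes moved
per clock hour (0–60), stored alongside its log(x+1) transform, the
variance-stabilising choice for zero-inflated activity data. Hours with
fewer than 30 observed minutes are flagged incomplete and are meant to
be excluded from seasonal means. Activity is non-increasing in `epsilon`
by construction; the tests assert this as a property.

## 5. Field thermal performance curves

Performance at a body temperature is defined as the 95th percentile of
minute acceleration within each 1 °C bin (half-open, `[k, k + 1)`), a
definition that targets the upper envelope of movement capacity while
ignoring the abundant sedentary minutes. Bins with fewer than 10 minutes
(`min_bin_count`) are dropped: an upper percentile on a handful of
points is dominated by single observations.

For group curves the percentile is computed per individual first and the
per-bin values averaged across individuals (`average_binned()`), so each
animal contributes equally; pooling all minutes first is available via
`bin_performance(by = "pooled")`. Whether a published group curve used
one path or the other is generally ambiguous; both are implemented and
the per-individual-then-average path is the default for group curves.
Note the per-individual percentile is noisier and biased low when few
active minutes fall in a bin, which attenuates the curve's *height* but
not the *location* of its maximum — the quantity of interest here.

The smooth is a penalized cubic B-spline (P-spline): `basis_dim = 10`
equally spaced cubic B-splines over the observed bin range with a
second-order difference penalty, smoothing parameter chosen by
generalized cross-validation over a 33-point log-spaced grid on
$\lambda \in 10^{[-4, 4]}$. The tests verify the GCV choice against a
ten-times-denser grid search. When several individuals' bins are fitted
together, per-individual intercept offsets shrunk by a ridge penalty
(default weight 1) absorb level differences; the reported curve is the
population-level smooth. This is a deliberate simplification of a full
random-smooth GAMM: the acceptance surface of the package is the
recovery of *P_max* and *T_opt*, not curve-for-curve equality with a
mixed-model smoother, and a transparent penalized regression makes the
smoothing choice auditable. `mgcv` serves as an independent cross-check
in the test suite, never as the implementation.

*P_max* is the maximum of the 0.1 °C prediction grid and *T_opt* its
temperature, with ties broken toward the lower temperature. The grid
covers the observed range only, so no extrapolated maxima are possible;
a maximum at a grid edge is flagged `boundary` (the data do not identify
an interior optimum), and a flat curve is flagged indeterminate rather
than yielding an arbitrary *T_opt*.

## 6. Known-fate survival

With detection probability 1, the likelihood is a product of binomial
terms: individual *i* contributes $\phi_i$ for each survived occasion
and $1 - \phi_i$ for a death, with
$\phi_i = \mathrm{logit}^{-1}(x_i'\beta)$ constant across occasions
within an individual (covariate effects are season-long; time-varying
survival is out of scope). Censored animals contribute only their fully
observed survived occasions — an animal is never assumed dead.

Daily surveys are collapsed to occasions of `occasion_length_days`
(default 7) over `n_occasions` (default 13, a 13-week spring). The
published analyses this design mirrors do not state their occasion
structure; weekly occasions are a documented assumption, and the
occasion arithmetic (entry at the occasion containing the tracking
start, death assigned to the occasion containing the death date,
censoring after the last occasion fully observed alive) is pinned by
worked examples in the tests.

The MLE uses BFGS from a zero start with analytic gradient. The
log-likelihood is evaluated through `plogis(eta, log.p = TRUE)`, which
is exact for any $\eta$; this matters because a clipped likelihood is
flat in the clipped region and can trap a line search at an absurd
overshoot. (The exported `kf_loglik()` keeps the conventional
$10^{-12}$ clipping as a guard for user-supplied extreme coefficients.)
Covariates are z-scored internally and coefficients reported on both
scales. The covariance is the inverse observed information
$X'\,\mathrm{diag}\{(s_i + d_i)\phi_i(1-\phi_i)\}\,X$. A data set with
no deaths has its MLE on the boundary ($\hat\phi = 1$): the fit is
flagged, reported with seasonal survival 1 and SE 0, and no Wald
covariance is produced — a Wald interval is meaningless on the boundary
and a one-sided profile bound should be used instead.

Seasonal survival is $\hat\phi^{n}$ with delta-method SE
$|n\,\hat\phi^{n}(1-\hat\phi)|\sqrt{x'Vx}$. AICc uses
$n_\mathrm{eff}$ = total at-risk intervals (the MARK convention for
known-fate models; switchable to number of animals), and `model_table()`
ranks candidate formulas with Akaike weights and the conventional
support flag at ΔAICc < 2. Non-converging or rank-deficient models are
listed with their failure reason and excluded from ranking.

## 7. The synthetic world

The generators state one fixed world; their defaults are not tuned to
make tests pass.

* **Environment** (`env_config`): five microhabitats (full shade,
  partial shade, open, tree, burrow) share a diel sinusoid peaking at
  15:00 with amplitude 10 °C around a seasonal mean of 28 °C —
  a realistic austral-spring regime for an arid-zone agamid — plus
  additive habitat offsets (−6 to +4 °C, burrow most buffered, open
  hottest) and Gaussian sensor noise (SD 1 °C). Copper models log
  hourly; the generator is *not* a biophysical heat-flux model, and the
  offsets stand in for radiation/convection differences it does not
  resolve.
* **Behaviour** (`gen_lizard_tb`): a thermoconformer sits at the mean
  available temperature; a thermoregulator is pulled from there toward
  the *T_set* midpoint by `tracking_gain` and clamped to the
  instantaneous envelope of available temperatures — behavioural
  thermoregulation cannot beat the best available microhabitat. This
  pull-and-clamp rule is a stand-in, not a mechanistic model of lizard
  decision-making; it exists to make the *E*-index endpoints exact
  (gain 0 with identical habitats gives *E* = 0; gain 1 with the
  midpoint inside the envelope gives *E* = 1).
* **Performance and bouts** (`true_performance`, `gen_accel`): bout
  starts are Bernoulli per minute at `bout_rate`/60 (the minute-resolution
  thinning of a Poisson process) with one-minute bouts; 6 bouts/h
  (≈10 % active minutes) reproduces the abundant sedentary periods of
  field accelerometry. Within a bout the magnitude follows a Gaussian
  curve with peak 1 m/s² at 36.6 °C (the published field optimum for
  this species guild), breadth 5 °C and sedentary baseline 0.05 m/s²;
  the two emitted axes decompose the magnitude at a uniformly random
  angle, so only the resultant is meaningful.
* **Survival** (`gen_encounter_histories`): per-occasion survival from a
  logit-linear model, death-terminated histories, optional independent
  censoring, staggered entry.

Every generator draws from its own seeded stream and restores the
caller's RNG state, and every generator output round-trips through the
text schemas `read_traces()` validates.

What a green recovery test establishes is therefore limited: it shows
the estimators invert *this* generative world (correct arithmetic,
binning, smoothing and likelihood code), not that the world captures
real lizards. Real data add measurement structure the generators omit —
autocorrelated behaviour, heterogeneous per-individual calibrations,
accelerometer drift and gaps, non-Gaussian performance curves,
informative censoring — and the pipeline's defaults should be revisited
against them.

## 8. Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere (T_set bounds, per-bin percentiles).
* Spline: basis dimension 10, second-order difference penalty, GCV over
  33 log-spaced $\lambda$ values; at least `max(4, basis_dim)` bins are
  required per fit, and smaller cells surface as reason codes in
  `per_individual_metrics()` rather than errors.
* Ties in *T_opt* extraction break toward the lower temperature; grid
  resolution 0.1 °C.
* `epsilon` for movement: $10^{-6}$ m/s², configurable.
* Likelihood: exact log-sigmoid evaluation inside the optimizer;
  $10^{-12}$ clipping only in the exported likelihood guard.
* $d_e = 0$ seasons yield `NA` effectiveness with a flag; zero-variance
  surface temperatures, empty traces, rank-deficient designs and fate
  records outside tracking windows raise informative errors.
* Seed handling: generators never touch the global RNG stream.

## 9. Known limitations

* The TPC smoother fits binned percentiles — the percentile definition
  is the package's contract. (Fitting raw minutes is possible by passing
  a frame with `bin_center = tb_mean`, `perf_p95 = accel_mean` to
  `fit_tpc()`, but is not a supported default.) Per-individual
  percentile attenuation biases *P_max* low in sparse bins.
* Survival is single-season, constant-φ, with non-informative censoring
  assumed; no time-varying covariates, no Kaplan–Meier/Cox machinery,
  no MARK `.inp` export.
* The copper-model generator does not model instantaneous heat-flux
  equilibrium; offsets are phenomenological.
* GPS/home-range analysis and mixed-model hypothesis tests of seasonal
  effects are upstream/downstream of this package: it emits the
  per-individual seasonal tables those analyses consume.
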