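# thermofate

Thermal ecology of free-ranging ectotherms from biologging data. The
package implements, as one tested pipeline, the analysis chain used in
field studies of heliothermic lizards that carry temperature loggers,
radio transmitters and accelerometers:

1. **Body-temperature calibration.** Internal body temperature is
   predicted from externally logged surface temperature through an
   ordinary-least-squares calibration
   `T_b,predict = a + b * T_surf` fitted on laboratory thermal-gradient
   pairs, with the preferred range *T_set* estimated per sex as the
   interquartile range of gradient body temperatures.
2. **Thermoregulation indices** (Hertz et al. convention). Hourly
   deviations of body temperature (*d_b*, accuracy of thermoregulation)
   and of copper-model operative temperatures (*d_e*, thermal quality of
   habitat) from *T_set*, aggregated per individual and season into the
   effectiveness of thermoregulation

   *E* = 1 − (mean *d_b* / mean *d_e*),

   where *E* = 1 is precise thermoregulation, *E* = 0 thermoconformity,
   and *E* < 0 avoidance of the preferred range.
3. **Activity budgets.** Two-axis accelerometer streams are reduced to
   per-minute resultant accelerations; a minute counts as moved when its
   mean changes from the previous minute's, giving minutes moved per hour
   (log(x+1)-transformed for analysis).
4. **Field thermal performance curves.** Performance at a body
   temperature is the 95th percentile of minute acceleration per 1 °C
   bin; a penalized cubic B-spline (smoothing parameter by GCV) fitted to
   the binned points yields the maximum performance *P_max* and the
   thermal optimum *T_opt* (the temperature at the curve maximum).
5. **Known-fate survival.** Encounter histories from daily telemetry are
   collapsed to fixed-length occasions and fitted by maximising the
   product-of-binomials likelihood with logit-linked individual
   covariates; seasonal survival is the per-occasion estimate raised to
   the number of occasions with a delta-method SE, and candidate models
   are ranked by AICc (support at ΔAICc < 2).

Every stage has a synthetic-data generator with known ground truth
(operative-temperature environments, behaviour-rule lizards, bout-process
accelerometers, gradient trials, encounter histories), so the full
pipeline can be validated by parameter recovery without any field data.

## Worked example

```r
library(thermofate)
set.seed(0)

## 1. Surface-to-body calibration from laboratory gradient pairs
pairs <- gen_gradient_pairs(intercept = 1.770, slope = 1.058,
                            n = 5000, noise_sd = 0.5, seed = 1)
fit_surface_calibration(pairs)
#> Surface-to-body calibration: Tb = 1.725 + 1.059 * Tsurf
#>   n = 5000 pairs, R^2 = 0.993, residual SD = 0.506 degC

## 2. Thermoregulation indices over a synthetic spring
tset <- tset_range("female", lower = 27, upper = 33.8)
env  <- gen_environment(env_config(season_length_days = 30, rng_seed = 2))
liz  <- gen_lizard_tb(env, behaviour_config("thermoregulator",
                                            tset_low = 27, tset_high = 33.8,
                                            tracking_gain = 0.8), seed = 3)
seasonal_indices(hourly_db(window_filter(liz), tset),
                 hourly_de(window_filter(env), tset))
#>   lizard_id season   mean_db  mean_de   e_index n_hours
#> 1     liz_1 spring 0.3776473 2.944373 0.8717393     480
```

The lizard tracks its preferred range imperfectly (gain 0.8), so its mean
deviation (0.38 °C) is far below the habitat's (2.94 °C): *E* ≈ 0.87,
an effective thermoregulator.

```r
## 3. Field thermal performance curve from accelerometry
##    (5 lizards, 2 days, true Gaussian peak at 36.6 degC)
tpc <- fit_tpc(bin_performance(minutes))   # see scripts in ?fit_tpc
tpc
#> Thermal performance curve [group]
#>   T_opt = 36.3 degC, P_max = 1.010 m/s^2
#>   edf = 9.91, lambda = 0.0001, bins over 15.5-44.5 degC
```

The bin–spline–argmax chain recovers the generator's true optimum
(36.6 °C) and peak (1 m/s²) to within the resolution expected from two
days of data.

```r
## 4. Known-fate survival with covariates and AICc ranking
##    (60 simulated animals; truth has sex and performance effects)
model_table(hist, list(null = ~1, sex = ~sex, sex_pmax = ~sex + pmax), cov)
#>      model K    loglik     aicc delta_aicc       weight support
#> 1 sex_pmax 3 -116.6226 239.2939    0.00000 9.995001e-01    TRUE
#> 2      sex 2 -125.2907 254.6057   15.31184 4.729976e-04   FALSE
#> 3     null 1 -129.1661 260.3402   21.04630 2.689281e-05   FALSE

seasonal_survival(kf_fit(hist, ~sex, cov), n_occasions = 13,
                  profile = c(sex = 1))$estimate
#> [1] 0.5610906
```

Model selection puts all the weight on the generating covariates, and the
derived 13-occasion male survival compounds the per-occasion estimate.

A thin command-line wrapper over the same functions is installed at
`system.file("cli/thermofate.R", package = "thermofate")` with
subcommands `ingest`, `calibrate`, `thermoreg`, `activity`, `tpc` and
`survive`.

## Validation script

`scripts/acceptance.R` re-runs the package's headline validation
end-to-end: it regenerates synthetic inputs whose ground truth is set to
published field estimates for an agamid lizard (calibration coefficients,
female upper *T_set*, sex-specific spring survival, field *T_opt*),
pushes them through the full pipeline (OLS calibration, quantile *T_set*
estimation, known-fate MLE, the accelerometer → minute → bin → spline
*T_opt* chain, and the exact *E*-index endpoints), and writes the
recovered values as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness flows from `--seed`; the run takes about two minutes on
one CPU.
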