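#' @title Synthetic-data generators with known ground truth
#' @description Every pipeline stage in this package can be exercised on
#'   generated data whose true parameters are known, so downstream estimates
#'   (calibration coefficients, T_set bounds, E, T_opt, P_max, survival)
#'   can be checked by recovery. Each generator draws from its own seeded
#'   stream and leaves the global RNG state untouched.
#' @name synthetic-data
NULL

# Evaluate `code` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

default_habitats <- function() {
  c(full_shade = -4, partial_shade = -2, open = 4, tree = 0, burrow = -6)
}

#' Configuration for the synthetic operative-temperature environment
#'
#' Describes one season of operative temperatures recorded by copper
#' physical models in five microhabitats. The shared signal is a diel
#' sinusoid (peak at 15:00 local) around a seasonal mean; each habitat adds
#' a constant offset, plus independent Gaussian sensor noise.
#'
#' @param season_length_days Days of record (default 91, one meteorological
#'   season).
#' @param day_mean_amp Diel sinusoid amplitude, deg C.
#' @param season_mean Seasonal mean temperature, deg C.
#' @param microhabitat_offsets Named numeric vector of additive habitat
#'   offsets (deg C); defaults cover the five field categories
#'   `full_shade`, `partial_shade`, `open`, `tree`, `burrow`.
#' @param noise_sd Sensor noise SD, deg C (>= 0).
#' @param time_step Recording interval in minutes (default 60: copper
#'   models log hourly).
#' @param rng_seed Integer seed.
#' @param start Start timestamp (default first day of austral spring).
#' @return A list of class `env_config`.
#' @export
env_config <- function(season_length_days = 91L,
                       day_mean_amp = 10,
                       season_mean = 28,
                       microhabitat_offsets = default_habitats(),
                       noise_sd = 1,
                       time_step = 60L,
                       rng_seed = 1L,
                       start = as.POSIXct("2018-10-01 00:00:00",
                                          tz = "UTC")) {
  stopifnot(season_length_days >= 1L, noise_sd >= 0, time_step >= 1L)
  if (is.null(names(microhabitat_offsets)) ||
      any(!nzchar(names(microhabitat_offsets)))) {
    stop("microhabitat_offsets must be a named vector")
  }
  unknown <- setdiff(names(microhabitat_offsets), names(default_habitats()))
  if (length(unknown) > 0L) {
    stop("unknown habitat name(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(season_length_days = as.integer(season_length_days),
                 day_mean_amp = day_mean_amp,
                 season_mean = season_mean,
                 microhabitat_offsets = microhabitat_offsets,
                 noise_sd = noise_sd,
                 time_step = as.integer(time_step),
                 rng_seed = as.integer(rng_seed),
                 start = start),
            class = "env_config")
}

diel_sinusoid <- function(ts, mean, amp) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  mean + amp * cos(2 * pi * (h - 15) / 24)
}

#' Generate copper-model operative temperature traces
#'
#' One `temperature_trace` per microhabitat (one copper model per
#' category), sharing the configured diel sinusoid, with habitat offsets
#' applied additively and independent Gaussian noise per reading.
#' Reproducible for a fixed `rng_seed`.
#'
#' @param cfg An [env_config()].
#' @return A `temperature_trace` data frame (`sensor_id`, `entity =
#'   "copper_model"`, `microhabitat`, `timestamp`, `temp_c`) with the true
#'   generating parameters in `attr(, "truth")`.
#' @export
gen_environment <- function(cfg) {
  stopifnot(inherits(cfg, "env_config"))
  ts <- seq(cfg$start,
            by = cfg$time_step * 60,
            length.out = cfg$season_length_days * 24L * 60L %/% cfg$time_step)
  base <- diel_sinusoid(ts, cfg$season_mean, cfg$day_mean_amp)
  habs <- names(cfg$microhabitat_offsets)
  out <- with_local_seed(cfg$rng_seed, {
    do.call(rbind, lapply(habs, function(h) {
      data.frame(sensor_id = paste0("cm_", h),
                 entity = "copper_model",
                 microhabitat = h,
                 timestamp = ts,
                 temp_c = base + cfg$microhabitat_offsets[[h]] +
                   stats::rnorm(length(ts), 0, cfg$noise_sd))
    }))
  })
  rownames(out) <- NULL
  attr(out, "truth") <- cfg
  class(out) <- c("temperature_trace", "data.frame")
  out
}

#' Behavioural configuration for a synthetic lizard
#'
#' @param mode `"thermoregulator"` or `"thermoconformer"`.
#' @param tset_low,tset_high Preferred-range bounds, deg C
#'   (`tset_low < tset_high`).
#' @param tracking_gain In `[0, 1]`: 0 gives pure conformity, 1 perfect
#'   tracking of the T_set midpoint (within the available envelope).
#' @param tb_noise_sd Body-temperature noise SD, deg C.
#' @return A list of class `behaviour_config`.
#' @export
behaviour_config <- function(mode = c("thermoregulator", "thermoconformer"),
                             tset_low = 27, tset_high = 33.8,
                             tracking_gain = 1, tb_noise_sd = 0.5) {
  mode <- match.arg(mode)
  stopifnot(tset_low < tset_high,
            tracking_gain >= 0, tracking_gain <= 1, tb_noise_sd >= 0)
  structure(list(mode = mode, tset_low = tset_low, tset_high = tset_high,
                 tracking_gain = tracking_gain, tb_noise_sd = tb_noise_sd),
            class = "behaviour_config")
}

#' Simulate a lizard body-temperature trace from an environment
#'
#' At each time step the available operative envelope is the range of
#' habitat temperatures. A thermoconformer takes the mean available
#' temperature; a thermoregulator starts there and is pulled toward the
#' T_set midpoint by `tracking_gain`, clamped to the envelope (behavioural
#' thermoregulation cannot beat the best available microhabitat). Gaussian
#' noise is added last. The pull-and-clamp rule is a synthetic stand-in,
#' not a mechanistic behaviour model.
#'
#' @param env A `temperature_trace` of copper-model records.
#' @param beh A [behaviour_config()].
#' @param seed Integer seed.
#' @param lizard_id Sensor id for the output trace.
#' @return A `temperature_trace` (`entity = "lizard"`).
#' @export
gen_lizard_tb <- function(env, beh, seed = 1L, lizard_id = "liz_1") {
  stopifnot(inherits(beh, "behaviour_config"))
  if (is.null(env) || nrow(env) == 0L) stop("empty environment")
  key <- as.numeric(env$timestamp)
  ts <- sort(unique(key))
  mean_te <- rowsum(env$temp_c, key)[, 1L] /
    rowsum(rep(1, length(key)), key)[, 1L]
  min_te <- tapply(env$temp_c, key, min)
  max_te <- tapply(env$temp_c, key, max)
  ord <- order(as.numeric(names(mean_te)))
  mean_te <- mean_te[ord]; min_te <- min_te[ord]; max_te <- max_te[ord]
  tb <- if (beh$mode == "thermoconformer") {
    mean_te
  } else {
    mid <- (beh$tset_low + beh$tset_high) / 2
    pulled <- mean_te + beh$tracking_gain * (mid - mean_te)
    pmin(pmax(pulled, min_te), max_te)
  }
  tb <- with_local_seed(seed,
    tb + stats::rnorm(length(tb), 0, beh$tb_noise_sd))
  out <- data.frame(sensor_id = lizard_id, entity = "lizard",
                    microhabitat = NA_character_,
                    timestamp = as.POSIXct(ts, origin = "1970-01-01",
                                           tz = "UTC"),
                    temp_c = as.numeric(tb))
  attr(out, "truth") <- beh
  class(out) <- c("temperature_trace", "data.frame")
  out
}

#' True thermal performance curve parameters
#'
#' Gaussian performance curve
#' `q(T) = baseline + (pmax_true - baseline) * exp(-(T - topt_true)^2 /
#' (2 * breadth^2))` governing locomotor acceleration during activity
#' bouts. Defaults place the peak at the field thermal optimum of an adult
#' bearded dragon (36.6 deg C) with a realistic bout intensity of
#' 1 m/s^2 over a 0.05 m/s^2 sedentary floor.
#'
#' @param topt_true Peak temperature, deg C.
#' @param pmax_true Peak acceleration, m/s^2 (`> baseline`).
#' @param breadth Gaussian SD of the curve, deg C (> 0).
#' @param baseline Sedentary acceleration magnitude, m/s^2 (>= 0).
#' @param bout_rate Expected activity bouts per hour (bouts last one
#'   minute; 6/h gives ~10% active minutes, leaving the abundant sedentary
#'   periods typical of field accelerometry).
#' @return A list of class `true_performance`.
#' @export
true_performance <- function(topt_true = 36.6, pmax_true = 1,
                             breadth = 5, baseline = 0.05,
                             bout_rate = 6) {
  stopifnot(pmax_true > baseline, baseline >= 0, breadth > 0,
            bout_rate >= 0)
  structure(list(topt_true = topt_true, pmax_true = pmax_true,
                 breadth = breadth, baseline = baseline,
                 bout_rate = bout_rate),
            class = "true_performance")
}

perf_curve <- function(temp, perf) {
  perf$baseline + (perf$pmax_true - perf$baseline) *
    exp(-(temp - perf$topt_true)^2 / (2 * perf$breadth^2))
}

#' Simulate a two-axis accelerometer trace from a body-temperature trace
#'
#' Minutes are classified active/sedentary by a Poisson bout process
#' (`bout_rate` starts per hour, one-minute bouts). Within an active minute
#' every sample's magnitude is the Gaussian performance curve evaluated at
#' the (interpolated) body temperature plus Gaussian noise; sedentary
#' samples sit exactly at `baseline`. Each magnitude is decomposed onto the
#' X-heave/Y-surge axes at a uniformly random angle, so only the resultant
#' is meaningful.
#'
#' @param tb A lizard `temperature_trace`.
#' @param perf A [true_performance()].
#' @param hz Sampling rate per axis, Hz (default 6).
#' @param seed Integer seed.
#' @param noise_sd Within-bout magnitude noise SD, m/s^2.
#' @return An `accel_trace` data frame (`lizard_id`, `timestamp`, `x`, `y`)
#'   with the generating `true_performance` and the per-minute active
#'   indicator in attributes `"truth"` and `"active_minutes"`.
#' @export
gen_accel <- function(tb, perf, hz = 6L, seed = 1L, noise_sd = 0.05) {
  stopifnot(inherits(perf, "true_performance"), hz >= 1L, noise_sd >= 0)
  if (nrow(tb) == 0L) stop("empty body-temperature trace")
  t0 <- floor_minute(min(tb$timestamp))
  t1 <- floor_minute(max(tb$timestamp))
  minutes <- seq(t0, t1, by = 60)
  n_min <- length(minutes)
  tnum <- as.numeric(tb$timestamp)
  tb_min <- if (nrow(tb) == 1L) {
    rep(tb$temp_c, length(minutes))
  } else {
    stats::approx(tnum, tb$temp_c, xout = as.numeric(minutes), rule = 2)$y
  }
  n_samp <- 60L * hz
  with_local_seed(seed, {
    active <- stats::runif(n_min) < perf$bout_rate / 60
    mag_minute <- ifelse(active, perf_curve(tb_min, perf), perf$baseline)
    # per-sample magnitudes: noise only within bouts
    mag <- rep(mag_minute, each = n_samp)
    act_idx <- which(rep(active, each = n_samp))
    if (length(act_idx) > 0L && noise_sd > 0) {
      mag[act_idx] <- mag[act_idx] +
        stats::rnorm(length(act_idx), 0, noise_sd)
    }
    mag <- pmax(mag, 0)
    theta <- stats::runif(length(mag), 0, 2 * pi)
    ts <- rep(as.numeric(minutes), each = n_samp) +
      rep(seq_len(n_samp) - 1L, times = n_min) / hz
    out <- data.frame(
      lizard_id = tb$sensor_id[1L],
      timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
      x = mag * cos(theta),
      y = mag * sin(theta))
    attr(out, "truth") <- perf
    attr(out, "active_minutes") <- data.frame(minute = minutes,
                                              active = active)
    class(out) <- c("accel_trace", "data.frame")
    out
  })
}

#' Generate paired surface/body gradient calibration data
#'
#' Surface temperatures are uniform over `surface_range`; body temperature
#' follows the linear relation `intercept + slope * surface` plus Gaussian
#' noise. With `noise_sd = 0`, ordinary least squares recovers the
#' coefficients to machine precision.
#'
#' @param intercept,slope True calibration coefficients.
#' @param n Number of pairs (>= 2).
#' @param noise_sd Body-temperature noise SD, deg C.
#' @param seed Integer seed.
#' @param surface_range Range of surface temperatures, deg C (default the
#'   20--40 span of a laboratory thermal gradient).
#' @return A data frame with columns `surface` and `body`.
#' @export
gen_gradient_pairs <- function(intercept, slope, n, noise_sd = 0.5,
                               seed = 1L, surface_range = c(20, 40)) {
  if (n < 2L) stop("need at least 2 pairs")
  with_local_seed(seed, {
    surface <- stats::runif(n, surface_range[1L], surface_range[2L])
    body <- intercept + slope * surface + stats::rnorm(n, 0, noise_sd)
    out <- data.frame(surface = surface, body = body)
    attr(out, "truth") <- list(intercept = intercept, slope = slope,
                               noise_sd = noise_sd)
    out
  })
}

#' Generate a laboratory thermal-gradient body-temperature trace
#'
#' Simulates one individual's gradient trial: readings every
#' `reading_interval_min` minutes drawn from a Gaussian selected-temperature
#' distribution, preceded by an acclimation period of the same distribution
#' that [estimate_tset()] should discard.
#'
#' @param lizard_id Sensor id.
#' @param mean,sd Gaussian parameters of selected body temperature, deg C.
#' @param n_readings Post-acclimation readings (default 720: 24 h at one
#'   reading per 2 min).
#' @param acclimation_h Hours of acclimation readings prepended (default 12).
#' @param reading_interval_min Minutes between readings (default 2).
#' @param seed Integer seed.
#' @param start Trial start timestamp.
#' @return A `temperature_trace` (`entity = "lizard"`).
#' @export
gen_gradient_trace <- function(lizard_id, mean, sd, n_readings = 720L,
                               acclimation_h = 12, reading_interval_min = 2L,
                               seed = 1L,
                               start = as.POSIXct("2018-06-01 08:00:00",
                                                  tz = "UTC")) {
  stopifnot(n_readings >= 1L, sd >= 0)
  n_acc <- as.integer(round(acclimation_h * 60 / reading_interval_min))
  n <- n_acc + n_readings
  ts <- seq(start, by = reading_interval_min * 60, length.out = n)
  out <- with_local_seed(seed, {
    data.frame(sensor_id = lizard_id, entity = "lizard",
               microhabitat = NA_character_, timestamp = ts,
               temp_c = stats::rnorm(n, mean, sd))
  })
  attr(out, "truth") <- list(mean = mean, sd = sd)
  class(out) <- c("temperature_trace", "data.frame")
  out
}

#' True parameters for known-fate survival simulation
#'
#' @param betas Named numeric vector of logit-scale coefficients; names
#'   must match columns produced by `model.matrix(~ ...)` on the covariate
#'   table, with `"(Intercept)"` first.
#' @param n_occasions Number of survey occasions (default 13 weekly
#'   occasions spanning an austral spring).
#' @param occasion_length_days Days per occasion (default 7).
#' @return A list of class `survival_truth`.
#' @export
survival_truth <- function(betas, n_occasions = 13L,
                           occasion_length_days = 7L) {
  stopifnot(n_occasions >= 1L, occasion_length_days >= 1L,
            is.numeric(betas), !is.null(names(betas)))
  structure(list(betas = betas, n_occasions = as.integer(n_occasions),
                 occasion_length_days = as.integer(occasion_length_days)),
            class = "survival_truth")
}

#' Simulate known-fate encounter histories
#'
#' Per-occasion survival for individual i is
#' `phi_i = plogis(x_i' beta)`, constant across occasions. Death ends a
#' history; optional independent censoring (probability `censor_rate` per
#' occasion, applied before the survival trial) ends it with a `censored`
#' state. Staggered entry is supported through an optional
#' `first_occasion` column in `covariates`.
#'
#' @param truth A [survival_truth()].
#' @param covariates Data frame with `lizard_id` plus the covariate columns
#'   named in `truth$betas` (intercept-only models need only `lizard_id`).
#' @param seed Integer seed.
#' @param censor_rate Per-occasion censoring probability in `[0, 1)`.
#' @return An `encounter_history` data frame with columns `lizard_id`,
#'   `occasion`, `state` (`survived`/`died`/`censored`); true per-individual
#'   `phi` in `attr(, "truth")`.
#' @export
gen_encounter_histories <- function(truth, covariates, seed = 1L,
                                    censor_rate = 0) {
  stopifnot(inherits(truth, "survival_truth"),
            censor_rate >= 0, censor_rate < 1)
  if (!"lizard_id" %in% names(covariates)) {
    stop("covariates must contain lizard_id")
  }
  vars <- setdiff(names(truth$betas), "(Intercept)")
  missing <- setdiff(vars, names(covariates))
  if (length(missing) > 0L) {
    stop("covariate column(s) missing for betas: ",
         paste(missing, collapse = ", "))
  }
  X <- if (length(vars) == 0L) {
    matrix(1, nrow(covariates), 1L, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(stats::reformulate(vars), covariates)
  }
  if (!identical(colnames(X), names(truth$betas))) {
    stop("beta layout mismatch: design columns are ",
         paste(colnames(X), collapse = ", "))
  }
  phi <- stats::plogis(drop(X %*% truth$betas))
  first <- if ("first_occasion" %in% names(covariates)) {
    as.integer(covariates$first_occasion)
  } else rep(1L, nrow(covariates))
  with_local_seed(seed, {
    rows <- vector("list", nrow(covariates))
    for (i in seq_len(nrow(covariates))) {
      occs <- integer(0); states <- character(0)
      for (occ in seq.int(first[i], truth$n_occasions)) {
        if (censor_rate > 0 && stats::runif(1) < censor_rate) {
          occs <- c(occs, occ); states <- c(states, "censored")
          break
        }
        alive <- stats::runif(1) < phi[i]
        occs <- c(occs, occ)
        states <- c(states, if (alive) "survived" else "died")
        if (!alive) break
      }
      rows[[i]] <- data.frame(lizard_id = covariates$lizard_id[i],
                              occasion = occs, state = states)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(betas = truth$betas, phi = phi)
    class(out) <- c("encounter_history", "data.frame")
    out
  })
}
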