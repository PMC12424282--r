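#' Estimate the preferred body-temperature range (T_set) per sex
#'
#' The preferred range of a gradient-housed individual is the interquartile
#' range of its selected body temperatures after discarding an acclimation
#' period. Sex-level bounds are the means of the per-individual bounds.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' Individuals whose trace does not extend past the acclimation window, or
#' whose post-acclimation record is degenerate (lower bound equal to the
#' upper), are excluded with a warning; if all individuals are excluded the
#' function errors.
#'
#' @param traces A `temperature_trace` containing one gradient trial per
#'   individual (`sensor_id` = lizard id).
#' @param sex_table Data frame with columns `lizard_id` and `sex`.
#' @param acclimation_h Hours dropped from the start of each trace
#'   (default 12).
#' @param probs Lower/upper quantile probabilities (default `c(0.25, 0.75)`).
#' @return A data frame of class `tset_range`, one row per sex, with
#'   columns `sex`, `lower`, `upper`, `n_individuals`, plus the
#'   per-individual bounds in `attr(, "individuals")`.
#' @export
estimate_tset <- function(traces, sex_table, acclimation_h = 12,
                          probs = c(0.25, 0.75)) {
  ids <- unique(traces$sensor_id)
  rows <- lapply(ids, function(id) {
    tr <- traces[traces$sensor_id == id, , drop = FALSE]
    cutoff <- min(tr$timestamp) + acclimation_h * 3600
    keep <- tr$timestamp >= cutoff
    if (!any(keep)) {
      warning("individual '", id, "' has no post-acclimation data; excluded")
      return(NULL)
    }
    q <- stats::quantile(tr$temp_c[keep], probs = probs, names = FALSE,
                         type = 7)
    if (q[1L] >= q[2L]) {
      warning("individual '", id, "' has a degenerate preferred range ",
              "(lower >= upper); excluded")
      return(NULL)
    }
    data.frame(lizard_id = id, lower = q[1L], upper = q[2L])
  })
  ind <- do.call(rbind, rows)
  if (is.null(ind) || nrow(ind) == 0L) {
    stop("no individual yields a usable preferred-temperature range")
  }
  ind <- merge(ind, sex_table[c("lizard_id", "sex")], by = "lizard_id")
  if (nrow(ind) == 0L) stop("no sex information for any individual")
  out <- do.call(rbind, lapply(split(ind, ind$sex), function(g) {
    data.frame(sex = g$sex[1L], lower = mean(g$lower),
               upper = mean(g$upper), n_individuals = nrow(g))
  }))
  rownames(out) <- NULL
  attr(out, "individuals") <- ind
  class(out) <- c("tset_range", "data.frame")
  out
}

#' Construct a preferred-range (T_set) table directly
#'
#' Convenience constructor for the object [estimate_tset()] returns, used
#' when the bounds are already known.
#'
#' @param sex Character vector of sexes.
#' @param lower,upper Bound vectors, deg C (`lower < upper` elementwise).
#' @param n_individuals Optional counts.
#' @return A `tset_range` data frame.
#' @export
tset_range <- function(sex, lower, upper, n_individuals = NA_integer_) {
  stopifnot(all(lower < upper))
  out <- data.frame(sex = sex, lower = lower, upper = upper,
                    n_individuals = n_individuals)
  class(out) <- c("tset_range", "data.frame")
  out
}

#' Fit the linear surface-to-body temperature calibration
#'
#' Ordinary least squares of internal body temperature on externally logged
#' surface temperature, yielding the affine correction used to predict
#' field body temperature from transmitter surface readings.
#'
#' @param pairs Data frame with columns `surface` and `body` (deg C).
#' @return A list of class `calibration_model` with `intercept`, `slope`,
#'   `r_squared`, `n_pairs`, `residual_sd`.
#' @examples
#' m <- fit_surface_calibration(data.frame(surface = 0:2, body = c(1, 3, 5)))
#' c(m$intercept, m$slope)  # 1, 2
#' @export
fit_surface_calibration <- function(pairs) {
  if (nrow(pairs) < 2L) stop("need at least 2 pairs")
  if (length(unique(pairs$surface)) < 2L) {
    stop("surface temperatures have zero variance; cannot fit calibration")
  }
  fit <- stats::lm(body ~ surface, data = pairs)
  co <- stats::coef(fit)
  # noiseless (exactly affine) input is legitimate here; silence the
  # "essentially perfect fit" warning summary.lm emits for it
  sm <- suppressWarnings(summary(fit))
  structure(list(intercept = unname(co[1L]),
                 slope = unname(co[2L]),
                 r_squared = sm$r.squared,
                 n_pairs = nrow(pairs),
                 residual_sd = sm$sigma),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Surface-to-body calibration: Tb = %.3f + %.3f * Tsurf\n", x$intercept,
    x$slope))
  cat(sprintf("  n = %d pairs, R^2 = %.3f, residual SD = %.3f degC\n",
              x$n_pairs, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Apply a surface calibration to a temperature trace
#'
#' Transforms each surface reading through the fitted affine map, producing
#' the predicted body-temperature trace. The result is marked predicted via
#' `attr(, "predicted")`.
#'
#' @param surf A `temperature_trace` of surface readings.
#' @param model A `calibration_model`.
#' @return The trace with `temp_c` replaced by
#'   `intercept + slope * temp_c`.
#' @export
apply_calibration <- function(surf, model) {
  stopifnot(inherits(model, "calibration_model"))
  surf$temp_c <- model$intercept + model$slope * surf$temp_c
  attr(surf, "predicted") <- TRUE
  surf
}

#' Paired bias between surface and body temperature
#'
#' Mean of the per-pair difference `surface - body`, its standard error and
#' the paired t statistic (df = n - 1). A positive mean indicates surface
#' temperature overestimates body temperature. When all differences are
#' identical the SE is zero and the t statistic is reported as `NA`
#' (degenerate).
#'
#' @param pairs Data frame with columns `surface` and `body`.
#' @return A list with `mean_diff`, `se`, `t`, `df`.
#' @export
paired_bias <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs")
  d <- pairs$surface - pairs$body
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  t_stat <- if (se == 0) {
    if (m == 0) 0 else NA_real_
  } else m / se
  list(mean_diff = m, se = se, t = t_stat, df = n - 1L)
}

#' Persist / load a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns the model.
#' @export
write_calibration <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "calibration_model")
}
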