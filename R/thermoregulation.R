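#' Deviation of a temperature from the preferred range
#'
#' The Hertz-style deviation underlying both the accuracy of
#' thermoregulation (d_b, body temperatures) and the thermal quality of the
#' habitat (d_e, operative temperatures): zero inside `[lower, upper]`,
#' otherwise the distance to the nearer bound. Vectorised over `temp`.
#'
#' @param temp Temperature(s), deg C.
#' @param lower,upper Preferred-range bounds (`lower < upper`).
#' @return Non-negative deviations, same length as `temp`.
#' @examples
#' deviation(c(30, 36, 25.5), lower = 27, upper = 33.8)  # 0, 2.2, 1.5
#' @export
deviation <- function(temp, lower, upper) {
  stopifnot(lower < upper)
  pmax(lower - temp, temp - upper, 0)
}

# Resolve the (lower, upper) bounds for one sex from a tset_range table.
tset_bounds <- function(tset, sex = NULL) {
  if (is.numeric(tset) && length(tset) == 2L) {
    return(c(lower = tset[1L], upper = tset[2L]))
  }
  stopifnot(is.data.frame(tset))
  if (nrow(tset) > 1L) {
    if (is.null(sex)) stop("tset has multiple rows; supply sex")
    tset <- tset[tset$sex == sex, , drop = FALSE]
    if (nrow(tset) != 1L) stop("no preferred range for sex '", sex, "'")
  }
  c(lower = tset$lower[1L], upper = tset$upper[1L])
}

hourly_mean_deviation <- function(ts, temp, lower, upper) {
  dev <- deviation(temp, lower, upper)
  lt <- as.POSIXlt(ts, tz = "UTC")
  key <- paste(format(ts, "%Y-%m-%d", tz = "UTC"),
               sprintf("%02d", lt$hour))
  agg <- tapply(dev, key, mean)
  parts <- strsplit(names(agg), " ")
  data.frame(date = as.Date(vapply(parts, `[`, "", 1L)),
             hour = as.integer(vapply(parts, `[`, "", 2L)),
             value = as.numeric(agg), row.names = NULL)
}

#' Hourly accuracy of thermoregulation (d_b)
#'
#' Mean deviation of predicted body temperature from the sex-specific
#' preferred range, per clock hour. Hours without readings are absent, not
#' zero. The trace should already be restricted to the daily analysis
#' window (see [window_filter()]).
#'
#' @param tb A predicted body-temperature `temperature_trace` for one
#'   lizard.
#' @param tset A `tset_range` table (or numeric `c(lower, upper)`).
#' @param sex Sex used to pick the range when `tset` has one row per sex.
#' @return A `deviation_series` data frame: `entity_id`, `date`, `hour`,
#'   `value` (deg C, >= 0).
#' @export
hourly_db <- function(tb, tset, sex = NULL) {
  b <- tset_bounds(tset, sex)
  out <- hourly_mean_deviation(tb$timestamp, tb$temp_c, b["lower"],
                               b["upper"])
  out <- cbind(entity_id = tb$sensor_id[1L], out)
  class(out) <- c("deviation_series", "data.frame")
  out
}

#' Hourly thermal quality of the habitat (d_e)
#'
#' For each clock hour, the deviation of each copper model's operative
#' temperature from the preferred range is computed (averaging within a
#' model if it has several readings that hour), then averaged across
#' models. Computed with the same sex-specific range as d_b so that the
#' effectiveness ratio is coherent.
#'
#' @param env A copper-model `temperature_trace` (several sensors).
#' @param tset,sex As in [hourly_db()].
#' @return A `deviation_series` data frame (`entity_id = "environment"`).
#' @export
hourly_de <- function(env, tset, sex = NULL) {
  b <- tset_bounds(tset, sex)
  per_model <- lapply(split(env, env$sensor_id), function(tr) {
    hourly_mean_deviation(tr$timestamp, tr$temp_c, b["lower"], b["upper"])
  })
  all <- do.call(rbind, per_model)
  key <- paste(all$date, sprintf("%02d", all$hour))
  agg <- tapply(all$value, key, mean)
  k <- sort(unique(key))
  parts <- strsplit(k, " ")
  out <- data.frame(entity_id = "environment",
                    date = as.Date(vapply(parts, `[`, "", 1L)),
                    hour = as.integer(vapply(parts, `[`, "", 2L)),
                    value = as.numeric(agg[k]),
                    row.names = NULL)
  class(out) <- c("deviation_series", "data.frame")
  out
}

#' Effectiveness of thermoregulation
#'
#' `E = 1 - mean_db / mean_de`. E of 1 indicates body temperatures held in
#' the preferred range regardless of the environment; 0 indicates
#' thermoconformity (body no better than environment); negative values
#' indicate active avoidance of the preferred range. When `mean_de = 0`
#' the habitat is perfectly benign and the ratio is undefined: `NA` is
#' returned and flagged via `attr(, "undefined")`.
#'
#' @param mean_db,mean_de Season-mean deviations (deg C, >= 0); vectorised.
#' @return E values (dimensionless, <= 1).
#' @examples
#' e_index(0, 3)   # 1: perfect thermoregulation
#' e_index(2, 2)   # 0: thermoconformity
#' e_index(6, 4)   # -0.5: avoidance of the preferred range
#' @export
e_index <- function(mean_db, mean_de) {
  if (any(mean_db < 0, na.rm = TRUE) || any(mean_de < 0, na.rm = TRUE)) {
    stop("mean deviations must be non-negative")
  }
  out <- ifelse(mean_de == 0, NA_real_, 1 - mean_db / mean_de)
  if (anyNA(out)) {
    attr(out, "undefined") <- which(mean_de == 0)
  }
  out
}

#' Seasonal thermoregulation indices per individual
#'
#' Restricts the hourly d_b and d_e series to hours where both exist,
#' averages each within season, and computes one effectiveness value per
#' season as the ratio of those means (ratio-of-means, not mean of hourly
#' ratios, which is unstable when hourly d_e approaches zero;
#' `method = "mean_of_ratios"` averages hourly `1 - db/de` instead,
#' dropping hours with `de = 0`).
#'
#' @param db A `deviation_series` from [hourly_db()].
#' @param de A `deviation_series` from [hourly_de()].
#' @param lizard_id Identifier for the output rows (defaults to the d_b
#'   series' entity).
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @return A `thermo_indices` data frame: `lizard_id`, `season`,
#'   `mean_db`, `mean_de`, `e_index`, `n_hours`. Seasons with no
#'   overlapping hours are absent.
#' @export
seasonal_indices <- function(db, de, lizard_id = NULL,
                             method = c("ratio_of_means",
                                        "mean_of_ratios")) {
  method <- match.arg(method)
  if (is.null(lizard_id)) lizard_id <- as.character(db$entity_id[1L])
  key_db <- paste(db$date, db$hour)
  key_de <- paste(de$date, de$hour)
  common <- intersect(key_db, key_de)
  if (length(common) == 0L) stop("d_b and d_e series share no hours")
  i_db <- match(common, key_db)
  i_de <- match(common, key_de)
  season <- assign_season(db$date[i_db])
  merged <- data.frame(season = season,
                       db = db$value[i_db], de = de$value[i_de])
  out <- do.call(rbind, lapply(split(merged, merged$season, drop = TRUE),
    function(g) {
      mean_db <- mean(g$db)
      mean_de <- mean(g$de)
      e <- if (method == "ratio_of_means") {
        as.numeric(e_index(mean_db, mean_de))
      } else {
        ok <- g$de > 0
        if (!any(ok)) NA_real_ else mean(1 - g$db[ok] / g$de[ok])
      }
      data.frame(lizard_id = lizard_id, season = g$season[1L],
                 mean_db = mean_db, mean_de = mean_de, e_index = e,
                 n_hours = nrow(g))
    }))
  rownames(out) <- NULL
  class(out) <- c("thermo_indices", "data.frame")
  out
}
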