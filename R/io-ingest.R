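#' Read and validate a logger or metadata file
#'
#' Reads one of the four delimited-text schemas used throughout the package
#' and returns a validated, typed data frame. All files are comma-separated,
#' UTF-8, with ISO-8601 timestamps (`YYYY-MM-DD HH:MM:SS`) or dates
#' (`YYYY-MM-DD`). Malformed rows are reported with their file line numbers
#' (header = line 1).
#'
#' Schemas:
#' \describe{
#'   \item{temperature}{`sensor_id, entity, microhabitat, timestamp, temp_c`.
#'     `entity` is `"lizard"` or `"copper_model"`; `microhabitat` is empty
#'     for lizards and required for copper models. Timestamps must be
#'     strictly increasing within a sensor.}
#'   \item{acceleration}{`lizard_id, timestamp, x, y` — two-axis (X-heave,
#'     Y-surge) accelerometer samples, nominally 6 Hz; gaps are allowed.}
#'   \item{lizards}{`lizard_id, sex, mass_g, tracked_from, tracked_to`.}
#'   \item{fates}{`lizard_id, date, status` with `status` one of
#'     `alive`, `dead`, `censored`; at most one terminal record per lizard
#'     and no records after it.}
#' }
#'
#' @param path Path to a CSV file.
#' @param schema One of `"temperature"`, `"acceleration"`, `"lizards"`,
#'   `"fates"`.
#' @return A data frame of the corresponding class
#'   (`temperature_trace`, `accel_trace`, `lizard_records`, `fate_records`).
#'   An empty file with a valid header returns a zero-row frame with a
#'   warning.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sensor_id,entity,microhabitat,timestamp,temp_c",
#'              "cm1,copper_model,open,2018-10-01 05:00:00,24.5",
#'              "cm1,copper_model,open,2018-10-01 06:00:00,26.0"), f)
#' tr <- read_traces(f, "temperature")
#' nrow(tr)
#' @export
read_traces <- function(path,
                        schema = c("temperature", "acceleration",
                                   "lizards", "fates")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- schema_columns(schema)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[required]
  if (nrow(df) == 0L) {
    warning("file ", path, " has a header but no data rows")
  }
  switch(schema,
    temperature  = validate_temperature(df),
    acceleration = validate_acceleration(df),
    lizards      = validate_lizards(df),
    fates        = validate_fates(df))
}

schema_columns <- function(schema) {
  switch(schema,
    temperature  = c("sensor_id", "entity", "microhabitat",
                     "timestamp", "temp_c"),
    acceleration = c("lizard_id", "timestamp", "x", "y"),
    lizards      = c("lizard_id", "sex", "mass_g",
                     "tracked_from", "tracked_to"),
    fates        = c("lizard_id", "date", "status"))
}

# Line number in the file for data row i (header is line 1).
file_line <- function(i) i + 1L

parse_ts <- function(x, what = "timestamp") {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(strptime(x, fmts[1L], tz = "UTC"))
  for (f in fmts[-1L]) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L) {
    stop("unparseable ", what, " at file line(s) ",
         paste(file_line(utils::head(bad, 5L)), collapse = ", "))
  }
  out
}

parse_num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0L) {
    stop("non-numeric ", what, " at file line(s) ",
         paste(file_line(utils::head(bad, 5L)), collapse = ", "))
  }
  out
}

check_monotone <- function(ts, by, what = "timestamp") {
  for (id in unique(by)) {
    idx <- which(by == id)
    d <- diff(as.numeric(ts[idx]))
    if (any(d == 0)) {
      stop("duplicated ", what, " for '", id, "' at file line ",
           file_line(idx[which(d == 0)[1L] + 1L]))
    }
    if (any(d < 0)) {
      stop("non-increasing ", what, " for '", id, "' at file line ",
           file_line(idx[which(d < 0)[1L] + 1L]))
    }
  }
  invisible(TRUE)
}

validate_temperature <- function(df) {
  df$timestamp <- parse_ts(df$timestamp)
  df$temp_c <- parse_num(df$temp_c, "temp_c")
  if (any(!is.finite(df$temp_c))) {
    stop("non-finite temp_c at file line(s) ",
         paste(file_line(which(!is.finite(df$temp_c))), collapse = ", "))
  }
  bad_entity <- which(!df$entity %in% c("lizard", "copper_model"))
  if (length(bad_entity) > 0L) {
    stop("entity must be 'lizard' or 'copper_model'; offending line(s) ",
         paste(file_line(bad_entity), collapse = ", "))
  }
  df$microhabitat[df$microhabitat == ""] <- NA_character_
  bad_hab <- which(df$entity == "copper_model" & is.na(df$microhabitat))
  if (length(bad_hab) > 0L) {
    stop("copper_model rows need a microhabitat; offending line(s) ",
         paste(file_line(bad_hab), collapse = ", "))
  }
  df$microhabitat[df$entity == "lizard"] <- NA_character_
  if (nrow(df) > 0L) check_monotone(df$timestamp, df$sensor_id)
  class(df) <- c("temperature_trace", "data.frame")
  df
}

validate_acceleration <- function(df) {
  df$timestamp <- parse_ts(df$timestamp)
  df$x <- parse_num(df$x, "x")
  df$y <- parse_num(df$y, "y")
  if (nrow(df) > 0L) check_monotone(df$timestamp, df$lizard_id)
  class(df) <- c("accel_trace", "data.frame")
  df
}

validate_lizards <- function(df) {
  df$mass_g <- parse_num(df$mass_g, "mass_g")
  df$tracked_from <- as.Date(parse_ts(df$tracked_from, "tracked_from"))
  df$tracked_to <- as.Date(parse_ts(df$tracked_to, "tracked_to"))
  bad_sex <- which(!df$sex %in% c("male", "female"))
  if (length(bad_sex) > 0L) {
    stop("sex must be 'male' or 'female'; offending line(s) ",
         paste(file_line(bad_sex), collapse = ", "))
  }
  bad <- which(df$tracked_from > df$tracked_to | df$mass_g <= 0)
  if (length(bad) > 0L) {
    stop("invalid tracking window or mass at file line(s) ",
         paste(file_line(bad), collapse = ", "))
  }
  class(df) <- c("lizard_records", "data.frame")
  df
}

validate_fates <- function(df) {
  df$date <- as.Date(parse_ts(df$date, "date"))
  bad <- which(!df$status %in% c("alive", "dead", "censored"))
  if (length(bad) > 0L) {
    stop("status must be alive/dead/censored; offending line(s) ",
         paste(file_line(bad), collapse = ", "))
  }
  for (id in unique(df$lizard_id)) {
    idx <- which(df$lizard_id == id)
    idx <- idx[order(df$date[idx])]
    term <- which(df$status[idx] != "alive")
    if (length(term) > 1L) {
      stop("more than one terminal record for '", id, "' (file line ",
           file_line(idx[term[2L]]), ")")
    }
    if (length(term) == 1L && term < length(idx)) {
      stop("records after terminal record for '", id, "' (file line ",
           file_line(idx[term + 1L]), ")")
    }
  }
  class(df) <- c("fate_records", "data.frame")
  df
}

#' Write a typed collection back to its delimited-text schema
#'
#' Inverse of [read_traces()]: the written file re-reads to the same records
#' (up to float formatting).
#'
#' @param x A data frame returned by [read_traces()] or by one of the
#'   synthetic-data generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("timestamp")) {
    if (col %in% names(df)) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d %H:%M:%OS3", tz = "UTC")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign Southern-Hemisphere meteorological seasons
#'
#' September--November is spring, December--February summer, March--May
#' autumn and June--August winter.
#'
#' @param date A `Date` (or timestamp) vector.
#' @return A factor with levels `spring`, `summer`, `autumn`, `winter`.
#' @examples
#' assign_season(as.Date(c("2018-10-15", "2019-01-01", "2019-06-30")))
#' @export
assign_season <- function(date) {
  m <- as.integer(format(as.Date(date, tz = "UTC"), "%m"))
  out <- character(length(m))
  out[m %in% c(9L, 10L, 11L)] <- "spring"
  out[m %in% c(12L, 1L, 2L)] <- "summer"
  out[m %in% c(3L, 4L, 5L)] <- "autumn"
  out[m %in% c(6L, 7L, 8L)] <- "winter"
  factor(out, levels = c("spring", "summer", "autumn", "winter"))
}

#' Restrict a trace to the daily analysis window
#'
#' Keeps records whose local clock hour lies in `[start_hour, end_hour)`
#' (half-open: a record at exactly `end_hour:00` is excluded). The default
#' window 05:00--21:00 covers the diel activity period of a heliothermic
#' lizard. Idempotent.
#'
#' @param x A data frame with a `timestamp` column.
#' @param start_hour,end_hour Integers with
#'   `0 <= start_hour < end_hour <= 24`.
#' @return `x` with out-of-window rows dropped.
#' @export
window_filter <- function(x, start_hour = 5L, end_hour = 21L) {
  stopifnot(start_hour >= 0L, start_hour < end_hour, end_hour <= 24L)
  h <- as.POSIXlt(x$timestamp, tz = "UTC")$hour
  out <- x[h >= start_hour & h < end_hour, , drop = FALSE]
  rownames(out) <- NULL
  out
}

floor_minute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

#' Build the per-minute record table pairing body temperature and movement
#'
#' Averages the resultant acceleration and the predicted body temperature
#' within each calendar minute (floored, not rolling) and joins the two
#' streams. Minutes present in only one stream are dropped; the number
#' dropped is reported in the `"n_dropped"` attribute.
#'
#' @param tb A `temperature_trace` for one lizard (predicted body
#'   temperature).
#' @param accel An `accel_trace` for the same lizard.
#' @param scale,offset Affine raw-count to m/s^2 conversion applied to each
#'   accelerometer axis before the resultant (see [resultant()]).
#' @return A data frame of class `minute_records` with columns
#'   `lizard_id`, `minute` (POSIXct, unique, sorted), `accel_mean` (m/s^2)
#'   and `tb_mean` (deg C).
#' @seealso [detect_moved()], [bin_performance()]
#' @export
minute_table <- function(tb, accel, scale = 1, offset = 0) {
  if (nrow(tb) == 0L || nrow(accel) == 0L) {
    stop("minute_table needs non-empty temperature and acceleration traces")
  }
  res <- resultant(accel$x, accel$y, scale = scale, offset = offset)
  am <- aggregate_minutes(floor_minute(accel$timestamp), res)
  tm <- aggregate_minutes(floor_minute(tb$timestamp), tb$temp_c)
  common <- intersect(am$minute, tm$minute)
  if (length(common) == 0L) {
    stop("temperature and acceleration streams share no minutes")
  }
  n_dropped <- (nrow(am) - length(common)) + (nrow(tm) - length(common))
  common <- sort(common)
  out <- data.frame(
    lizard_id = accel$lizard_id[1L],
    minute = as.POSIXct(common, origin = "1970-01-01", tz = "UTC"),
    accel_mean = am$value[match(common, am$minute)],
    tb_mean = tm$value[match(common, tm$minute)]
  )
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("minute_records", "data.frame")
  out
}

aggregate_minutes <- function(minute, value) {
  key <- as.numeric(minute)
  sums <- rowsum(value, key)
  cnt <- rowsum(rep(1, length(key)), key)
  data.frame(minute = as.numeric(rownames(sums)),
             value = sums[, 1L] / cnt[, 1L], row.names = NULL)
}
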