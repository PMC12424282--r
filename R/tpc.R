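#' Bin minute records into per-degree performance summaries
#'
#' Field performance at a body temperature is defined as the 95th
#' percentile of minute-mean acceleration within each 1 deg C bin
#' (half-open bins `[k, k + w)`; a value of exactly 30.0 falls in
#' `[30, 31)`). The high percentile captures the upper capacity for
#' movement while ignoring the abundant sedentary minutes. Percentiles use
#' interpolated order statistics (`stats::quantile` type 7). Bins with
#' fewer than `min_bin_count` minutes are dropped to stabilise the upper
#' percentile.
#'
#' @param minutes A `minute_records` data frame with `tb_mean` and
#'   `accel_mean` (and `lizard_id` when `by = "individual"`).
#' @param bin_width Bin width, deg C (default 1).
#' @param min_bin_count Minimum minutes per retained bin (default 10).
#' @param prob Percentile (default 0.95).
#' @param by `"pooled"` (all minutes together) or `"individual"` (one set
#'   of bins per lizard).
#' @return A `binned_performance` data frame: (`lizard_id`,) `bin_center`,
#'   `perf_p95`, `n_minutes`. Errors if no bin qualifies.
#' @seealso [average_binned()], [fit_tpc()]
#' @export
bin_performance <- function(minutes, bin_width = 1, min_bin_count = 10L,
                            prob = 0.95, by = c("pooled", "individual")) {
  by <- match.arg(by)
  keep <- is.finite(minutes$tb_mean) & is.finite(minutes$accel_mean)
  minutes <- minutes[keep, , drop = FALSE]
  bin_one <- function(df, id = NULL) {
    lo <- floor(df$tb_mean / bin_width) * bin_width
    agg <- split(df$accel_mean, lo)
    agg <- agg[vapply(agg, length, 1L) >= min_bin_count]
    if (length(agg) == 0L) return(NULL)
    out <- data.frame(
      bin_center = as.numeric(names(agg)) + bin_width / 2,
      perf_p95 = vapply(agg, stats::quantile, 0, probs = prob,
                        names = FALSE, type = 7),
      n_minutes = vapply(agg, length, 1L), row.names = NULL)
    if (!is.null(id)) out <- cbind(lizard_id = id, out)
    out[order(out$bin_center), , drop = FALSE]
  }
  out <- if (by == "pooled") {
    bin_one(minutes)
  } else {
    do.call(rbind, lapply(split(minutes, minutes$lizard_id),
                          function(g) bin_one(g, g$lizard_id[1L])))
  }
  if (is.null(out) || nrow(out) == 0L) {
    stop("no temperature bin reaches min_bin_count = ", min_bin_count)
  }
  rownames(out) <- NULL
  class(out) <- c("binned_performance", "data.frame")
  out
}

#' Average per-individual binned performance into a group curve
#'
#' For group-level curves the per-degree percentile is computed per
#' individual first and then averaged across individuals at each bin, so
#' every animal contributes equally regardless of how many minutes it
#' logged.
#'
#' @param binned Output of `bin_performance(..., by = "individual")`.
#' @return A pooled-format `binned_performance` frame; `n_minutes` is the
#'   total minutes behind each bin and `n_individuals` the contributing
#'   animals.
#' @export
average_binned <- function(binned) {
  stopifnot("lizard_id" %in% names(binned))
  out <- do.call(rbind, lapply(split(binned, binned$bin_center), function(g) {
    data.frame(bin_center = g$bin_center[1L],
               perf_p95 = mean(g$perf_p95),
               n_minutes = sum(g$n_minutes),
               n_individuals = nrow(g))
  }))
  out <- out[order(out$bin_center), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binned_performance", "data.frame")
  out
}

# Equally spaced cubic B-spline basis (P-spline setup): k basis functions
# over [xl, xr], evaluated at x.
pspline_basis <- function(x, xl, xr, k, degree = 3L) {
  ndx <- k - degree
  stopifnot(ndx >= 1L)
  dx <- (xr - xl) / ndx
  knots <- seq(xl - degree * dx, xr + degree * dx, by = dx)
  splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = TRUE)
}

#' Fit a penalized-spline thermal performance curve
#'
#' Penalized cubic B-spline (P-spline) regression of per-degree
#' performance on bin-centre temperature: `basis_dim` equally spaced cubic
#' B-splines with a second-order difference penalty, the smoothing
#' parameter chosen by generalized cross-validation over a log-spaced
#' grid. When `binned` carries several individuals, per-individual
#' intercept offsets shrunk by a ridge penalty absorb systematic level
#' differences; the reported curve is the population-level smooth. This is
#' a deliberately transparent stand-in for a full random-smooth GAMM: the
#' quantities of interest are the curve maximum and its temperature, not
#' curve-for-curve equality with a mixed-model fit.
#'
#' @param binned A `binned_performance` frame (>= `max(4, basis_dim)`
#'   rows per fit).
#' @param basis_dim Number of B-spline basis functions (default 10).
#' @param lambda_grid Smoothing-parameter grid (default
#'   `10^seq(-4, 4, length.out = 33)`).
#' @param grid_step Prediction-grid resolution, deg C (default 0.1).
#' @param ridge Ridge penalty on individual offsets (default 1).
#' @param group Label stored on the fit (used in error messages).
#' @return A list of class `tpc_fit`: `grid` (data frame `temp`, `pred`
#'   over the observed temperature range only), `pmax`, `topt`, `edf`,
#'   `lambda`, `gcv` (the GCV path), `boundary`, `indeterminate`.
#' @examples
#' b <- data.frame(bin_center = seq(20, 40), n_minutes = 50,
#'                 perf_p95 = 2 - 0.02 * (seq(20, 40) - 36)^2)
#' f <- fit_tpc(b)
#' c(f$topt, f$pmax)
#' @export
fit_tpc <- function(binned, basis_dim = 10L,
                    lambda_grid = 10^seq(-4, 4, length.out = 33),
                    grid_step = 0.1, ridge = 1, group = "group") {
  x <- binned$bin_center
  y <- binned$perf_p95
  n <- length(x)
  if (n < max(4L, basis_dim)) {
    stop("too few bins (", n, ") to fit group '", group,
         "' with basis_dim = ", basis_dim)
  }
  xl <- min(x); xr <- max(x)
  B <- pspline_basis(x, xl, xr, basis_dim)
  D <- diff(diag(basis_dim), differences = 2L)
  P0 <- crossprod(D)
  has_offsets <- "lizard_id" %in% names(binned) &&
    length(unique(binned$lizard_id)) > 1L
  if (has_offsets) {
    ids <- factor(binned$lizard_id)
    Z <- stats::model.matrix(~ 0 + ids)
    Bfull <- cbind(B, Z)
    pad <- function(lam) {
      pen <- matrix(0, ncol(Bfull), ncol(Bfull))
      pen[seq_len(basis_dim), seq_len(basis_dim)] <- lam * P0
      diag(pen)[-seq_len(basis_dim)] <- ridge
      pen
    }
  } else {
    Bfull <- B
    pad <- function(lam) lam * P0
  }
  BtB <- crossprod(Bfull)
  Bty <- crossprod(Bfull, y)
  gcv_of <- function(lam) {
    A <- BtB + pad(lam)
    coef <- solve(A, Bty)
    fitted <- drop(Bfull %*% coef)
    rss <- sum((y - fitted)^2)
    edf <- sum(diag(solve(A, BtB)))
    if (n - edf < 1e-8) return(list(gcv = Inf, coef = coef, edf = edf))
    list(gcv = n * rss / (n - edf)^2, coef = coef, edf = edf)
  }
  fits <- lapply(lambda_grid, gcv_of)
  gcv <- vapply(fits, `[[`, 0, "gcv")
  best <- which.min(gcv)
  coef <- fits[[best]]$coef
  grid_x <- seq(xl, xr, by = grid_step)
  Bg <- pspline_basis(grid_x, xl, xr, basis_dim)
  pred <- drop(Bg %*% coef[seq_len(basis_dim)])
  fit <- structure(list(
    group = group,
    grid = data.frame(temp = grid_x, pred = pred),
    edf = fits[[best]]$edf,
    lambda = lambda_grid[best],
    gcv = data.frame(lambda = lambda_grid, gcv = gcv),
    coef = coef,
    basis_dim = basis_dim,
    x_range = c(xl, xr)), class = "tpc_fit")
  ext <- extract_tpc(fit)
  fit$pmax <- ext$pmax
  fit$topt <- ext$topt
  fit$boundary <- ext$boundary
  fit$indeterminate <- ext$indeterminate
  fit
}

#' Extract maximum performance and thermal optimum from a fitted curve
#'
#' `pmax` is the maximum of the prediction grid and `topt` its
#' temperature, with ties broken toward the lower temperature. The grid
#' only covers the observed temperature range, so no extrapolated maxima
#' are reported; a maximum at either grid edge sets the `boundary` flag,
#' and a flat curve (range below `tol`) is flagged indeterminate.
#'
#' @param fit A `tpc_fit` (or any list with a `grid` data frame).
#' @param tol Flatness tolerance on the prediction range (default `1e-8`).
#' @return A list with `pmax`, `topt`, `boundary`, `indeterminate`.
#' @export
extract_tpc <- function(fit, tol = 1e-8) {
  g <- fit$grid
  idx <- which.max(g$pred)  # first max = lowest temperature on a tie
  flat <- diff(range(g$pred)) < tol
  list(pmax = g$pred[idx],
       topt = if (flat) NA_real_ else g$temp[idx],
       boundary = !flat && (idx == 1L || idx == nrow(g)),
       indeterminate = flat)
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("Thermal performance curve [%s]\n", x$group))
  cat(sprintf("  T_opt = %.1f degC, P_max = %.3f m/s^2%s\n",
              x$topt, x$pmax,
              if (isTRUE(x$boundary)) " (boundary maximum)" else ""))
  cat(sprintf("  edf = %.2f, lambda = %.3g, bins over %.1f-%.1f degC\n",
              x$edf, x$lambda, x$x_range[1L], x$x_range[2L]))
  invisible(x)
}

#' Per-individual seasonal TPC metrics
#'
#' Runs bin / fit / extract separately for each lizard and season,
#' producing the table a seasonal mixed-model analysis of P_max and T_opt
#' would consume. Cells with insufficient data are reported with a reason
#' code instead of estimates.
#'
#' @param minutes A `minute_records` frame for one or more lizards.
#' @param bin_width,min_bin_count,prob Passed to [bin_performance()].
#' @param basis_dim,lambda_grid,grid_step Passed to [fit_tpc()].
#' @return A data frame: `lizard_id`, `season`, `pmax`, `topt`,
#'   `boundary`, `n_bins`, `reason` (`"ok"` or why the cell is empty).
#' @export
per_individual_metrics <- function(minutes, bin_width = 1,
                                   min_bin_count = 10L, prob = 0.95,
                                   basis_dim = 10L,
                                   lambda_grid = 10^seq(-4, 4,
                                                        length.out = 33),
                                   grid_step = 0.1) {
  minutes$season <- assign_season(as.Date(minutes$minute, tz = "UTC"))
  cells <- split(minutes,
                 list(minutes$lizard_id, minutes$season), drop = TRUE)
  out <- lapply(cells, function(g) {
    row <- data.frame(lizard_id = g$lizard_id[1L],
                      season = g$season[1L],
                      pmax = NA_real_, topt = NA_real_, boundary = NA,
                      n_bins = NA_integer_, reason = "ok")
    res <- tryCatch({
      b <- bin_performance(g, bin_width = bin_width,
                           min_bin_count = min_bin_count, prob = prob)
      f <- fit_tpc(b, basis_dim = basis_dim, lambda_grid = lambda_grid,
                   grid_step = grid_step,
                   group = paste(row$lizard_id, row$season))
      row$pmax <- f$pmax; row$topt <- f$topt
      row$boundary <- f$boundary; row$n_bins <- nrow(b)
      row
    }, error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
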