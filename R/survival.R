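#' Build known-fate encounter histories from fate records
#'
#' Divides a season into `n_occasions` consecutive fixed-length occasions
#' and converts daily telemetry fate records into per-occasion states.
#' Individuals enter at the occasion containing the later of their
#' `tracked_from` date and the season start (staggered entry). A death is
#' assigned to the occasion containing the death date. A lost transmitter
#' contributes survived states for every occasion fully observed alive and
#' a `censored` marker at the next occasion — an animal is never assumed
#' dead. Daily surveys within an occasion collapse to a single state.
#'
#' @param fates A `fate_records` data frame (`lizard_id`, `date`,
#'   `status`).
#' @param lizards A `lizard_records` data frame (tracking windows).
#' @param season_start First day of occasion 1 (`Date`).
#' @param n_occasions Number of occasions (default 13).
#' @param occasion_length_days Days per occasion (default 7; daily surveys
#'   over a 13-week austral spring collapse to weekly occasions).
#' @return An `encounter_history` data frame: `lizard_id`, `occasion`,
#'   `state` in `survived`/`died`/`censored`.
#' @export
build_histories <- function(fates, lizards, season_start,
                            n_occasions = 13L, occasion_length_days = 7L) {
  season_start <- as.Date(season_start)
  L <- occasion_length_days
  season_end <- season_start + n_occasions * L - 1L
  occ_of <- function(d) as.integer(floor(as.numeric(d - season_start) / L)) + 1L
  occ_last_day <- function(k) season_start + k * L - 1L
  rows <- lapply(seq_len(nrow(lizards)), function(i) {
    id <- lizards$lizard_id[i]
    fr <- fates[fates$lizard_id == id, , drop = FALSE]
    fr <- fr[order(fr$date), , drop = FALSE]
    if (nrow(fr) > 0L &&
        (any(fr$date < lizards$tracked_from[i]) ||
         any(fr$date > lizards$tracked_to[i]))) {
      stop("fate record outside tracking window for '", id, "'")
    }
    entry <- max(lizards$tracked_from[i], season_start)
    if (entry > season_end) return(NULL)
    first_occ <- max(1L, occ_of(entry))
    death_date <- if (any(fr$status == "dead")) fr$date[fr$status == "dead"]
    censor_date <- if (any(fr$status == "censored"))
      fr$date[fr$status == "censored"]
    if (!is.null(death_date)) {
      docc <- min(occ_of(death_date), n_occasions)
      if (docc < first_occ) {
        stop("death before entry occasion for '", id, "'")
      }
      occs <- seq.int(first_occ, docc)
      states <- c(rep("survived", docc - first_occ), "died")
    } else {
      last_seen <- if (!is.null(censor_date)) censor_date else {
        min(lizards$tracked_to[i],
            if (nrow(fr) > 0L) max(fr$date) else lizards$tracked_to[i])
      }
      # fully observed alive through occasion k iff seen on its last day
      full <- which(occ_last_day(seq_len(n_occasions)) <= last_seen)
      last_full <- if (length(full) > 0L) max(full) else first_occ - 1L
      occs <- integer(0); states <- character(0)
      if (last_full >= first_occ) {
        occs <- seq.int(first_occ, last_full)
        states <- rep("survived", length(occs))
      }
      if (!is.null(censor_date) && last_full + 1L <= n_occasions) {
        occs <- c(occs, last_full + 1L)
        states <- c(states, "censored")
      }
      if (length(occs) == 0L) return(NULL)
    }
    data.frame(lizard_id = id, occasion = occs, state = states)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no encounter histories could be built")
  rownames(out) <- NULL
  class(out) <- c("encounter_history", "data.frame")
  out
}

# Sufficient statistics: per individual, survived-interval count and death
# indicator. Censored markers contribute no interval.
kf_sumstats <- function(histories) {
  ids <- unique(histories$lizard_id)
  s <- vapply(ids, function(id) {
    sum(histories$state[histories$lizard_id == id] == "survived")
  }, 0L)
  d <- vapply(ids, function(id) {
    sum(histories$state[histories$lizard_id == id] == "died")
  }, 0L)
  if (any(d > 1L)) stop("an individual cannot die more than once")
  data.frame(lizard_id = ids, s = as.numeric(s), d = as.numeric(d),
             row.names = NULL)
}

kf_design <- function(formula, data, ids) {
  formula <- stats::as.formula(formula)
  if (length(formula) == 3L) formula <- formula[-2L]  # drop phi ~ lhs
  vars <- all.vars(formula)
  if (length(vars) == 0L) {
    return(matrix(1, length(ids), 1L,
                  dimnames = list(NULL, "(Intercept)")))
  }
  if (is.null(data)) stop("covariate model needs a data argument")
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v) > 0L) {
    stop("covariate column(s) not in data: ",
         paste(missing_v, collapse = ", "))
  }
  idx <- match(ids, data$lizard_id)
  if (anyNA(idx)) {
    stop("no covariates for individual(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  stats::model.matrix(formula, data[idx, , drop = FALSE])
}

#' Known-fate log-likelihood
#'
#' The product-of-binomials likelihood for telemetered animals whose fate
#' is known with certainty: each at-risk interval of individual i
#' contributes `phi_i` if survived and `1 - phi_i` if it ended in death,
#' with `phi_i = plogis(x_i' beta)` constant across that individual's
#' occasions. Censored intervals contribute nothing beyond the survived
#' intervals that precede them. `phi` is clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param histories An `encounter_history` data frame.
#' @param betas Coefficient vector on the logit scale, in design-column
#'   order.
#' @param formula Covariate formula (RHS), default intercept-only `~ 1`;
#'   `phi ~ x` is accepted and the LHS ignored.
#' @param data Per-individual covariates (`lizard_id` + columns).
#' @return The log-likelihood (scalar).
#' @export
kf_loglik <- function(histories, betas, formula = ~1, data = NULL) {
  ss <- kf_sumstats(histories)
  X <- kf_design(formula, data, ss$lizard_id)
  if (length(betas) != ncol(X)) {
    stop("betas has length ", length(betas), " but the design has ",
         ncol(X), " column(s)")
  }
  phi <- stats::plogis(drop(X %*% betas))
  phi <- pmin(pmax(phi, 1e-12), 1 - 1e-12)
  sum(ss$s * log(phi) + ss$d * log(1 - phi))
}

#' Fit a known-fate survival model by maximum likelihood
#'
#' Maximizes the product-of-binomials likelihood with logit-linked
#' individual covariates by quasi-Newton (BFGS) from a zero start, with
#' analytic gradient. The coefficient covariance is the inverse observed
#' information. Numeric covariates are z-scored internally for stable
#' optimisation; coefficients are reported on both scales. A dataset with
#' no deaths puts the MLE on the boundary (`phi = 1`): the fit is returned
#' with `boundary = TRUE`, `loglik = 0` and no Wald covariance (a Wald SE
#' is meaningless there; use a one-sided profile bound instead).
#'
#' @param histories An `encounter_history` data frame.
#' @param formula RHS covariate formula (default `~ 1`).
#' @param data Per-individual covariate data frame (`lizard_id` + columns).
#' @param n_eff_unit Effective sample size convention for AICc:
#'   `"intervals"` (at-risk intervals, MARK's known-fate convention,
#'   default) or `"animals"`.
#' @return A list of class `known_fate_fit`: `betas` (standardized scale),
#'   `betas_raw`, `loglik`, `K`, `n_eff`, `aicc`, `vcov`, `phi_hat`,
#'   `boundary`, `formula`, plus the standardization (`centers`,
#'   `scales`).
#' @export
kf_fit <- function(histories, formula = ~1, data = NULL,
                   n_eff_unit = c("intervals", "animals")) {
  n_eff_unit <- match.arg(n_eff_unit)
  ss <- kf_sumstats(histories)
  X_raw <- kf_design(formula, data, ss$lizard_id)
  qrX <- qr(X_raw)
  if (qrX$rank < ncol(X_raw)) {
    aliased <- colnames(X_raw)[qrX$pivot[(qrX$rank + 1L):ncol(X_raw)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  # z-score non-intercept columns with positive spread
  centers <- rep(0, ncol(X_raw)); scales <- rep(1, ncol(X_raw))
  names(centers) <- names(scales) <- colnames(X_raw)
  X <- X_raw
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] == "(Intercept)") next
    sdj <- stats::sd(X[, j])
    if (is.finite(sdj) && sdj > 0) {
      centers[j] <- mean(X[, j]); scales[j] <- sdj
      X[, j] <- (X[, j] - centers[j]) / scales[j]
    }
  }
  n_eff <- if (n_eff_unit == "intervals") sum(ss$s + ss$d) else nrow(ss)
  K <- ncol(X)
  if (sum(ss$d) == 0) {
    fit <- structure(list(
      formula = formula, betas = NULL, betas_raw = NULL,
      loglik = 0, K = K, n_eff = n_eff,
      aicc = aicc(0, K, n_eff), vcov = NULL,
      phi_hat = rep(1, nrow(ss)), lizard_id = ss$lizard_id,
      boundary = TRUE, centers = centers, scales = scales,
      converged = TRUE), class = "known_fate_fit")
    return(fit)
  }
  # log(phi) and log(1 - phi) via plogis(log.p) stay exact for any eta,
  # so an overshooting line-search step is penalised rather than hitting a
  # flat clipped region.
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(ss$s * stats::plogis(eta, log.p = TRUE) +
           ss$d * stats::plogis(-eta, log.p = TRUE))
  }
  grad <- function(b) {
    phi <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, ss$s * (1 - phi) - ss$d * phi))
  }
  opt <- stats::optim(rep(0, K), nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  betas <- opt$par
  names(betas) <- colnames(X)
  phi <- stats::plogis(drop(X %*% betas))
  info <- crossprod(X, X * ((ss$s + ss$d) * phi * (1 - phi)))
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(vcov)) dimnames(vcov) <- list(colnames(X), colnames(X))
  # back-transform to the raw covariate scale
  betas_raw <- betas / scales
  if ("(Intercept)" %in% names(betas)) {
    betas_raw["(Intercept)"] <- betas["(Intercept)"] -
      sum((betas * centers / scales)[names(betas) != "(Intercept)"])
  }
  structure(list(
    formula = formula, betas = betas, betas_raw = betas_raw,
    loglik = -opt$value, K = K, n_eff = n_eff,
    aicc = aicc(-opt$value, K, n_eff), vcov = vcov,
    phi_hat = phi, lizard_id = ss$lizard_id,
    boundary = FALSE, centers = centers, scales = scales,
    converged = opt$convergence == 0), class = "known_fate_fit")
}

#' @export
print.known_fate_fit <- function(x, ...) {
  cat("Known-fate survival fit\n")
  if (x$boundary) {
    cat("  no deaths observed: phi on the boundary (phi_hat = 1)\n")
  } else {
    cat("  logit-scale coefficients (standardized covariates):\n")
    print(round(x$betas, 4))
  }
  cat(sprintf("  logLik = %.3f, K = %d, n_eff = %d, AICc = %.3f\n",
              x$loglik, x$K, x$n_eff, x$aicc))
  invisible(x)
}

#' Derived seasonal survival with delta-method standard error
#'
#' Cumulative survival over `n_occasions` occasions,
#' `S = phi(profile)^n`, for a covariate profile (defaults to the sample
#' mean, i.e. all standardized covariates at zero). The SE follows the
#' delta method through the logit link and the power:
#' `dS/d(eta) = n * phi^n * (1 - phi)`, so
#' `SE = |n * phi^n * (1 - phi)| * sqrt(x' V x)`.
#'
#' @param fit A `known_fate_fit`.
#' @param n_occasions Number of occasions to compound over.
#' @param profile Optional named vector of covariate values on the raw
#'   scale; unnamed covariates sit at their sample mean.
#' @return A list with `estimate`, `se`, `phi`.
#' @export
seasonal_survival <- function(fit, n_occasions, profile = NULL) {
  if (fit$boundary) {
    return(list(estimate = 1, se = 0, phi = 1))
  }
  nm <- names(fit$betas)
  x <- stats::setNames(rep(0, length(nm)), nm)
  if ("(Intercept)" %in% nm) x["(Intercept)"] <- 1
  if (!is.null(profile)) {
    for (v in names(profile)) {
      if (!v %in% nm) stop("profile names unknown coefficient: ", v)
      x[v] <- (profile[[v]] - fit$centers[v]) / fit$scales[v]
    }
  }
  eta <- sum(x * fit$betas)
  phi <- stats::plogis(eta)
  est <- phi^n_occasions
  se <- if (is.null(fit$vcov)) NA_real_ else {
    var_eta <- drop(t(x) %*% fit$vcov %*% x)
    abs(n_occasions * est * (1 - phi)) * sqrt(var_eta)
  }
  list(estimate = est, se = se, phi = phi)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1)/(n_eff - K - 1)`, with `n_eff` the
#' number of at-risk intervals (MARK's known-fate convention) or of
#' animals. Undefined (returned as `NA` with a warning) when
#' `n_eff <= K + 1`.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated parameters.
#' @param n_eff Effective sample size.
#' @return The AICc value.
#' @examples
#' aicc(-10, 2, 100)  # 24 + 12/97
#' @export
aicc <- function(loglik, K, n_eff) {
  if (n_eff <= K + 1) {
    warning("AICc undefined: n_eff <= K + 1")
    return(NA_real_)
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Fit and rank a candidate set of known-fate models
#'
#' Fits every formula, ranks converged fits by AICc, and reports
#' delta-AICc, Akaike weights (normalized over converged fits) and the
#' conventional support flag at delta < 2. Models that fail are listed
#' with the failure reason and excluded from ranking.
#'
#' @param histories An `encounter_history` data frame.
#' @param formulas Named list of RHS formulas, e.g.
#'   `list(null = ~1, sexXpmax = ~sex * pmax)`.
#' @param data Per-individual covariates.
#' @param n_eff_unit Passed to [kf_fit()].
#' @return A data frame sorted by AICc: `model`, `K`, `loglik`, `aicc`,
#'   `delta_aicc`, `weight`, `support`, `converged`, `note`; the fitted
#'   objects are attached as `attr(, "fits")`.
#' @export
model_table <- function(histories, formulas, data = NULL,
                        n_eff_unit = "intervals") {
  stopifnot(length(formulas) >= 2L, !is.null(names(formulas)))
  fits <- lapply(formulas, function(f) {
    tryCatch(kf_fit(histories, f, data, n_eff_unit = n_eff_unit),
             error = function(e) conditionMessage(e))
  })
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (is.character(f)) {
      data.frame(model = nm, K = NA_integer_, loglik = NA_real_,
                 aicc = NA_real_, converged = FALSE, note = f)
    } else {
      data.frame(model = nm, K = f$K, loglik = f$loglik, aicc = f$aicc,
                 converged = f$converged, note = "")
    }
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged & is.finite(tab$aicc))
  tab$delta_aicc <- NA_real_
  tab$weight <- NA_real_
  if (length(ok) > 0L) {
    tab$delta_aicc[ok] <- tab$aicc[ok] - min(tab$aicc[ok])
    w <- exp(-0.5 * tab$delta_aicc[ok])
    tab$weight[ok] <- w / sum(w)
  }
  tab$support <- !is.na(tab$delta_aicc) & tab$delta_aicc < 2
  ord <- order(is.na(tab$aicc), tab$aicc)
  tab <- tab[ord, c("model", "K", "loglik", "aicc", "delta_aicc",
                    "weight", "support", "converged", "note")]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}
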