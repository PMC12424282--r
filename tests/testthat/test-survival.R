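test_that("encounter histories follow entry, death and censoring rules", {
  start <- as.Date("2018-09-01")
  lizards <- data.frame(
    lizard_id = c("full", "dies", "lost"),
    sex = "male", mass_g = 400,
    tracked_from = c(start, start, start),
    tracked_to = c(start + 200, start + 200, start + 200))
  fates <- data.frame(
    lizard_id = c("full", "dies", "lost"),
    date = c(start + 13 * 7 - 1,   # alive on the last day of occasion 13
             start + 9,            # death on day 10
             start + 19),          # transmitter lost day 20
    status = c("alive", "dead", "censored"))
  h <- build_histories(fates, lizards, season_start = start,
                       n_occasions = 13, occasion_length_days = 7)

  full <- h[h$lizard_id == "full", ]
  expect_equal(nrow(full), 13L)
  expect_true(all(full$state == "survived"))

  dies <- h[h$lizard_id == "dies", ]          # day 10 is in occasion 2
  expect_equal(dies$state, c("survived", "died"))
  expect_equal(dies$occasion, 1:2)

  lost <- h[h$lizard_id == "lost", ]          # day 20 is inside occasion 3
  expect_equal(lost$state, c("survived", "survived", "censored"))
  expect_equal(lost$occasion, 1:3)

  # staggered entry: tracked_from inside occasion 3
  late <- data.frame(lizard_id = "late", sex = "female", mass_g = 300,
                     tracked_from = start + 16, tracked_to = start + 200)
  fl <- data.frame(lizard_id = "late", date = start + 90, status = "alive")
  hl <- build_histories(fl, late, season_start = start)
  expect_equal(min(hl$occasion), 3L)

  # fate outside the tracking window errors
  bad <- data.frame(lizard_id = "full", date = start + 300,
                    status = "alive")
  expect_error(build_histories(bad, lizards, season_start = start),
               "outside tracking window")
})

test_that("known-fate log-likelihood matches the binomial closed form", {
  # 4 one-occasion histories, 3 survived 1 died, phi = 0.75
  h <- make_histories(s = c(1, 1, 1, 0), d = c(0, 0, 0, 1))
  expect_equal(kf_loglik(h, qlogis(0.75)),
               3 * log(0.75) + log(0.25))

  # beta = 0: every at-risk interval contributes log(1/2)
  expect_equal(kf_loglik(h, 0), 4 * log(0.5))

  # all survive, beta large: loglik approaches 0 from below
  h2 <- make_histories(s = c(13, 13), d = c(0, 0))
  ll <- kf_loglik(h2, 15)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-4)

  expect_error(kf_loglik(h, c(0, 1)), "length")
})

test_that("intercept-only MLE equals the closed form on every instance", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:25, 1)
    s <- rpois(n, 8)
    d <- rbinom(n, 1, 0.3)
    if (sum(d) == 0) d[1] <- 1
    h <- make_histories(s, d)
    fit <- kf_fit(h)
    expect_equal(unname(plogis(fit$betas)), sum(s) / sum(s + d),
                 tolerance = 1e-6)
    expect_equal(fit$n_eff, sum(s + d))
  }

  # no deaths: boundary flagged, phi_hat = 1
  fitb <- kf_fit(make_histories(s = c(5, 5), d = c(0, 0)))
  expect_true(fitb$boundary)
  expect_equal(fitb$phi_hat, c(1, 1))
  expect_equal(seasonal_survival(fitb, 13)$estimate, 1)
  expect_equal(seasonal_survival(fitb, 13)$se, 0)
})

test_that("2-parameter MLE matches a grid-search oracle within 1e-3", {
  set.seed(23)
  cov <- data.frame(lizard_id = sprintf("L%02d", 1:10),
                    x = rnorm(10))
  truth <- survival_truth(c("(Intercept)" = 1.5, x = -1), n_occasions = 8)
  h <- gen_encounter_histories(truth, cov, seed = 29)
  fit <- kf_fit(h, ~x, cov)
  # oracle: dense grid over (intercept, slope) on the standardized scale
  ss <- thermofate:::kf_sumstats(h)
  xz <- scale(cov$x[match(ss$lizard_id, cov$lizard_id)])
  ll <- function(b0, b1) {
    eta <- b0 + b1 * xz
    sum(ss$s * plogis(eta, log.p = TRUE) +
          ss$d * plogis(-eta, log.p = TRUE))
  }
  b0g <- seq(fit$betas[1] - 0.25, fit$betas[1] + 0.25, by = 0.001)
  b1g <- seq(fit$betas[2] - 0.25, fit$betas[2] + 0.25, by = 0.001)
  grid <- outer(b0g, b1g, Vectorize(ll))
  best <- arrayInd(which.max(grid), dim(grid))
  expect_lt(abs(b0g[best[1]] - fit$betas[1]), 1e-3 + 1e-9)
  expect_lt(abs(b1g[best[2]] - fit$betas[2]), 1e-3 + 1e-9)
})

test_that("likelihood is invariant to history order and splitting", {
  h <- make_histories(s = c(6, 3, 9), d = c(1, 0, 1))
  beta <- qlogis(0.8)
  ll <- kf_loglik(h, beta)
  shuffled <- h[rev(seq_len(nrow(h))), ]
  expect_equal(kf_loglik(shuffled, beta), ll)
  # split one history into two with identical (absent) covariates
  split_h <- make_histories(s = c(6, 3, 4, 5), d = c(1, 0, 0, 1))
  expect_equal(kf_loglik(split_h, beta), ll)
})

test_that("AICc arithmetic and limits", {
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97)
  expect_equal(aicc(-10, 0, 50), 20)           # K = 0: plain -2 loglik
  expect_equal(aicc(-10, 2, 1e9), 24, tolerance = 1e-6)  # AICc -> AIC
  expect_warning(expect_true(is.na(aicc(-10, 5, 6))), "undefined")
})

test_that("delta-method seasonal survival matches hand arithmetic", {
  h <- make_histories(s = rep(9, 10), d = rep(1, 10))  # phi_hat = 0.9
  fit <- kf_fit(h)
  s13 <- seasonal_survival(fit, 13)
  expect_equal(s13$phi, 0.9, tolerance = 1e-6)
  expect_equal(s13$estimate, 0.9^13, tolerance = 1e-5)
  # delta method: se = n phi^n (1-phi) sqrt(var_eta)
  var_eta <- 1 / (100 * 0.9 * 0.1)
  expect_equal(s13$se, 13 * 0.9^13 * 0.1 * sqrt(var_eta), tolerance = 1e-4)
})

test_that("model table ranks by AICc with normalized weights", {
  set.seed(41)
  cov <- data.frame(lizard_id = sprintf("L%02d", 1:40),
                    sex = rep(0:1, 20), pmax = rnorm(40))
  truth <- survival_truth(c("(Intercept)" = 2.2, sex = 1.2, pmax = -1.2))
  h <- gen_encounter_histories(truth, cov, seed = 43)
  tab <- model_table(h, list(null = ~1, sex = ~sex,
                             sex_pmax = ~sex + pmax,
                             dup = ~1), cov)
  expect_equal(tab$delta_aicc[1], 0)
  expect_equal(sum(tab$weight, na.rm = TRUE), 1)
  expect_true(all(diff(tab$aicc) >= 0))
  # duplicate models share an AICc
  expect_equal(tab$aicc[tab$model == "null"], tab$aicc[tab$model == "dup"])
  # rank-deficient model is reported, not ranked
  cov$pmax2 <- cov$pmax
  tab2 <- model_table(h, list(ok = ~pmax, alias = ~pmax + pmax2), cov)
  expect_false(tab2$converged[tab2$model == "alias"])
  expect_match(tab2$note[tab2$model == "alias"], "rank deficient")
})

test_that("parameter recovery: fitted betas track the simulation truth", {
  # scaled-down recovery: 40 replicates of 30 individuals, one covariate
  set.seed(47)
  truth <- survival_truth(c("(Intercept)" = 2.5, x = -0.8),
                          n_occasions = 13)
  ests <- t(vapply(1:40, function(r) {
    cov <- data.frame(lizard_id = sprintf("L%02d", 1:30),
                      x = with_seed_rnorm(500 + r, 30))
    h <- gen_encounter_histories(truth, cov, seed = 900 + r)
    fit <- kf_fit(h, ~x, cov)
    if (fit$boundary) return(c(NA_real_, NA_real_))
    unname(fit$betas_raw)
  }, c(0, 0)))
  m <- colMeans(ests, na.rm = TRUE)
  se <- apply(ests, 2, stats::sd, na.rm = TRUE) / sqrt(sum(!is.na(ests[, 1])))
  # MLE has finite-sample bias away from truth; allow 3 MC SEs plus 10%
  expect_lt(abs(m[1] - 2.5), 3 * se[1] + 0.25)
  expect_lt(abs(m[2] + 0.8), 3 * se[2] + 0.08)
})
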