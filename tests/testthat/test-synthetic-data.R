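test_that("environment generator honours offsets, noise and seeds", {
  # zero noise, zero offsets: every habitat equals the shared sinusoid
  env <- flat_env(days = 1, noise_sd = 0)
  by_hab <- split(env$temp_c, env$microhabitat)
  for (h in names(by_hab)) expect_equal(by_hab[[h]], by_hab[["open"]])

  # additive offset: burrow = open - 5 at every step
  offs <- flat_offsets(); offs["burrow"] <- -5
  env2 <- gen_environment(env_config(season_length_days = 1,
                                     microhabitat_offsets = offs,
                                     noise_sd = 0, rng_seed = 3))
  expect_equal(env2$temp_c[env2$microhabitat == "burrow"],
               env2$temp_c[env2$microhabitat == "open"] - 5)

  # seed contract
  cfg <- env_config(season_length_days = 1, noise_sd = 1, rng_seed = 7)
  expect_identical(gen_environment(cfg), gen_environment(cfg))
  cfg2 <- env_config(season_length_days = 1, noise_sd = 1, rng_seed = 8)
  expect_false(identical(gen_environment(cfg)$temp_c,
                         gen_environment(cfg2)$temp_c))

  expect_error(env_config(microhabitat_offsets = c(lava = 2)),
               "unknown habitat")
  expect_error(env_config(noise_sd = -1))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(flat_env(noise_sd = 1, seed = 5))
  invisible(gen_gradient_pairs(0, 1, 10, seed = 6))
  expect_identical(.Random.seed, before)
})

test_that("lizard body-temperature rule: conformity, tracking, clamping", {
  # thermoconformer with no noise sits at the mean available temperature
  env <- flat_env(days = 1, noise_sd = 0)
  tb <- gen_lizard_tb(env, behaviour_config("thermoconformer",
                                            tb_noise_sd = 0))
  mean_te <- tapply(env$temp_c, as.numeric(env$timestamp), mean)
  expect_equal(unname(tb$temp_c), unname(as.numeric(mean_te)))

  # degenerate envelope: pull halfway toward 30 from 20 clamps back to 20
  env20 <- flat_env(days = 1, mean = 20, amp = 0, noise_sd = 0)
  reg <- behaviour_config("thermoregulator", tset_low = 25, tset_high = 35,
                          tracking_gain = 0.5, tb_noise_sd = 0)
  tb20 <- gen_lizard_tb(env20, reg)
  expect_equal(tb20$temp_c, rep(20, nrow(tb20)))

  # habitats {20,20,20,35,20}: mean 23 pulled halfway to 30 lands at 26.5,
  # inside the [20, 35] envelope
  offs <- flat_offsets(); offs["open"] <- 15
  env2 <- gen_environment(env_config(season_length_days = 1,
                                     day_mean_amp = 0, season_mean = 20,
                                     microhabitat_offsets = offs,
                                     noise_sd = 0))
  tb2 <- gen_lizard_tb(env2, reg)
  expect_equal(tb2$temp_c, rep(23 + 0.5 * (30 - 23), nrow(tb2)))

  # perfect tracking with the midpoint inside the envelope hits it exactly
  tb3 <- gen_lizard_tb(env2, behaviour_config("thermoregulator",
                                              tset_low = 25, tset_high = 35,
                                              tracking_gain = 1,
                                              tb_noise_sd = 0))
  expect_equal(tb3$temp_c, rep(30, nrow(tb3)))

  expect_error(gen_lizard_tb(env2[0, ], reg), "empty")
})

test_that("accelerometer generator reproduces the performance curve", {
  perf <- true_performance(topt_true = 36, pmax_true = 1.2, breadth = 4,
                           baseline = 0.1, bout_rate = 60)  # always active
  # constant body temperature at the optimum: resultant == pmax exactly
  tb <- make_tb_trace(rep(36, 30))
  acc <- gen_accel(tb, perf, hz = 6, seed = 1, noise_sd = 0)
  expect_equal(resultant(acc$x, acc$y), rep(1.2, nrow(acc)))

  # one breadth away: baseline + (pmax - baseline) * exp(-1/2)
  tb2 <- make_tb_trace(rep(36 + 4, 30))
  acc2 <- gen_accel(tb2, perf, hz = 6, seed = 1, noise_sd = 0)
  expect_equal(resultant(acc2$x, acc2$y),
               rep(0.1 + 1.1 * exp(-0.5), nrow(acc2)))

  # no bouts: resultant constant at baseline, downstream activity zero
  quiet <- true_performance(bout_rate = 0, baseline = 0.05)
  acc3 <- gen_accel(make_tb_trace(rep(30, 120)), quiet, seed = 2)
  expect_equal(resultant(acc3$x, acc3$y), rep(0.05, nrow(acc3)))
  mt <- minute_table(make_tb_trace(rep(30, 120)), acc3)
  act <- hourly_activity(detect_moved(mt), min_minutes = 1)
  expect_true(all(act$minutes_moved == 0))

  # sampling contract: 6 Hz on two axes, same length
  expect_equal(nrow(acc), 30 * 60 * 6)
})

test_that("gradient-pair generator supports exact OLS recovery", {
  p <- gen_gradient_pairs(1.770, 1.058, n = 200, noise_sd = 0, seed = 1)
  m <- fit_surface_calibration(p)
  expect_equal(m$intercept, 1.770, tolerance = 1e-10)
  expect_equal(m$slope, 1.058, tolerance = 1e-10)
  expect_equal(m$r_squared, 1)

  ident <- gen_gradient_pairs(0, 1, n = 50, noise_sd = 0, seed = 2)
  expect_equal(ident$body, ident$surface)
  expect_error(gen_gradient_pairs(0, 1, n = 1), "at least 2")
})

test_that("encounter-history generator matches binomial closed forms", {
  cov <- data.frame(lizard_id = sprintf("L%03d", 1:800))
  # beta = 0: per-occasion survival one half
  h <- gen_encounter_histories(
    survival_truth(c("(Intercept)" = 0), n_occasions = 13), cov, seed = 1)
  s <- sum(h$state == "survived"); d <- sum(h$state == "died")
  p_hat <- s / (s + d)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / (s + d)))

  # essentially infinite intercept: nobody dies
  h2 <- gen_encounter_histories(
    survival_truth(c("(Intercept)" = 20), n_occasions = 13), cov, seed = 2)
  expect_true(all(h2$state == "survived"))

  # phi = 0.9 over 13 occasions: cumulative survival ~ 0.9^13 = 0.254
  h3 <- gen_encounter_histories(
    survival_truth(c("(Intercept)" = qlogis(0.9)), n_occasions = 13),
    cov, seed = 3)
  surv13 <- tapply(h3$state == "survived", h3$lizard_id, sum) == 13
  truth <- 0.9^13
  expect_lt(abs(mean(surv13) - truth),
            3 * sqrt(truth * (1 - truth) / 800))

  expect_error(
    gen_encounter_histories(survival_truth(c("(Intercept)" = 0, mass = 1)),
                            cov),
    "missing")
})

test_that("generator output round-trips through io_ingest unchanged", {
  env <- flat_env(days = 1, noise_sd = 0.5, seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(env, f)
  back <- read_traces(f, "temperature")
  expect_equal(back$temp_c, env$temp_c, tolerance = 1e-9)
  expect_equal(back$timestamp, env$timestamp)
  expect_equal(back$microhabitat, env$microhabitat)

  acc <- gen_accel(make_tb_trace(rep(30, 2)), true_performance(), seed = 1)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_traces(acc, f2)
  back2 <- read_traces(f2, "acceleration")
  expect_equal(back2$x, acc$x, tolerance = 1e-9)
})
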