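# Shared fixture builders: everything is generated in code, no stored data.

flat_offsets <- function(value = 0) {
  stats::setNames(rep(value, 5),
                  c("full_shade", "partial_shade", "open", "tree", "burrow"))
}

# Environment whose five habitats are identical (offsets 0) -- the setting
# in which a noise-free thermoconformer has d_b == d_e exactly.
flat_env <- function(days = 1, mean = 28, amp = 10, noise_sd = 0,
                     time_step = 60, seed = 1) {
  gen_environment(env_config(
    season_length_days = days, day_mean_amp = amp, season_mean = mean,
    microhabitat_offsets = flat_offsets(), noise_sd = noise_sd,
    time_step = time_step, rng_seed = seed))
}

# Minimal minute_records frame from vectors (minutes on a fixed day).
make_minutes <- function(accel, tb = NULL, start = "2018-10-01 08:00:00",
                         step_min = 1, id = "liz_1") {
  n <- length(accel)
  data.frame(
    lizard_id = id,
    minute = seq(as.POSIXct(start, tz = "UTC"), by = step_min * 60,
                 length.out = n),
    accel_mean = accel,
    tb_mean = if (is.null(tb)) rep(NA_real_, n) else tb)
}

# One-lizard temperature trace from a vector of readings.
make_tb_trace <- function(values, start = "2018-10-01 08:00:00",
                          step_s = 60, id = "liz_1") {
  data.frame(sensor_id = id, entity = "lizard",
             microhabitat = NA_character_,
             timestamp = seq(as.POSIXct(start, tz = "UTC"), by = step_s,
                             length.out = length(values)),
             temp_c = values)
}

# Copper-model trace: one reading per model at a single hour.
make_env_hour <- function(values, start = "2018-10-01 08:00:00") {
  data.frame(sensor_id = paste0("cm_", seq_along(values)),
             entity = "copper_model",
             microhabitat = "open",
             timestamp = as.POSIXct(start, tz = "UTC"),
             temp_c = values)
}

# n standard-normal draws under a private seed.
with_seed_rnorm <- function(seed, n) {
  withr::with_seed(seed, stats::rnorm(n))
}

# Encounter history frame from survived counts and death flags.
make_histories <- function(s, d) {
  rows <- lapply(seq_along(s), function(i) {
    states <- c(rep("survived", s[i]), if (d[i] > 0) "died")
    data.frame(lizard_id = sprintf("L%02d", i),
               occasion = seq_along(states), state = states)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("encounter_history", "data.frame")
  out
}
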