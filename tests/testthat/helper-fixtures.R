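# Shared in-code fixtures. The medium-sized simulated run is built once per
# test session and reused by several test files.

tiny_farm <- function(n_cows = 6) {
  farm_config("T1", n_cows, n_cows * 9, n_cows, 1, 1, 2)
}

h1_farm <- function() farm_config("H1", 70, 625, 66, 2, 1, 3)

noiseless_error_model <- function() {
  error_model(daily_miss = 0, ghost_rate = 0, id_correct = 1,
              id_swap_share = 0,
              activity_confusion = default_activity_confusion(1),
              location_cooccur = 0, zone_base_error = 0,
              night_detect_drop = 0)
}

.fixture_env <- new.env(parent = emptyenv())

# 100 cows x 20 days with known error rates: shared by the parameter-recovery
# and structural-invariant tests.
recovery_run <- function() {
  if (is.null(.fixture_env$recovery)) {
    farm <- farm_config("R1", 100, 900, 100, 3, 2, 5)
    ht <- simulate_herd(farm, sim_config(seed = 421, n_days = 20))
    em <- error_model(daily_miss = 0.10, ghost_rate = 0.05,
                      id_correct = 0.80, id_swap_share = 0.5,
                      night_detect_drop = 0.10)
    emu <- emulate_system(ht, em, seed = 422)
    .fixture_env$recovery <- list(ht = ht, em = em, emu = emu)
  }
  .fixture_env$recovery
}

# balanced hourly-proportion table with known variance components
balanced_rows <- function(n_days, hours, hour_effects, sd_day, sd_resid) {
  stopifnot(length(hour_effects) == length(hours))
  day_eff <- stats::rnorm(n_days, 0, sd_day)
  g <- expand.grid(day = seq_len(n_days), hour = hours)
  g$proportion <- 0.9 + hour_effects[match(g$hour, hours)] +
    day_eff[g$day] + stats::rnorm(nrow(g), 0, sd_resid)
  g
}
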