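# Small grids/short durations keep these tests fast; the full-scale
# default experiment runs in the acceptance suite.

small_config <- function(seed = 1, ...) {
  experiment_config(
    seed = seed,
    activation_times_s = c(20, 40),
    step_um = list(ch1 = c(116.5, 130), ch2 = c(143.5, 130)),
    duration_s = 60,
    n_samples = 8001,
    ...
  )
}

test_that("experiment configs validate their schedule and grid", {
  expect_s3_class(experiment_config(), "fp_experiment_config")
  expect_error(experiment_config(activation_times_s = c(60, 50, 180)),
               class = "fp_config_error")
  expect_error(experiment_config(activation_times_s = c(60, 120, 500)),
               class = "fp_config_error")
  expect_error(experiment_config(step_um = list(ch1 = c(1, 2),
                                                ch2 = c(1, 2, 3))),
               class = "fp_config_error")
  # a schedule that drives the cavity beyond what the grid resolves
  expect_error(
    experiment_config(step_um = list(ch1 = c(3000, 130, 130),
                                     ch2 = c(143.5, 130, 130)),
                      n_samples = 2001),
    class = "fp_config_error")
})

test_that("simulation is deterministic under a fixed seed", {
  ds1 <- simulate_experiment(small_config(seed = 33))
  ds2 <- simulate_experiment(small_config(seed = 33))
  expect_identical(ds1$ground_truth, ds2$ground_truth)
  expect_identical(ds1$frames$ch1[[7]]$intensity,
                   ds2$frames$ch1[[7]]$intensity)
  ds3 <- simulate_experiment(small_config(seed = 34))
  expect_false(identical(ds1$frames$ch1[[7]]$intensity,
                         ds3$frames$ch1[[7]]$intensity))
})

test_that("zero-noise zero-schedule simulation is exactly constant", {
  cfg <- experiment_config(activation_times_s = numeric(0),
                           step_um = list(ch1 = numeric(0),
                                          ch2 = numeric(0)),
                           jitter_sd_pm = 0, intensity_sd = 0,
                           duration_s = 5, n_samples = 8001)
  ds <- simulate_experiment(cfg)
  ser <- track(ds)
  expect_equal(unique(ds$ground_truth$d_true_um),
               unname(cfg$initial_d_um))
  for (ch in c("ch1", "ch2")) {
    d <- ser$d_um[ser$channel == ch]
    expect_equal(stats::var(d), 0)
    expect_lt(abs(d[1] - cfg$initial_d_um[[ch]]), 1e-3)
  }
})

test_that("ground truth encodes the staircase and thermal drift", {
  cfg <- small_config()
  d <- fpsense:::ground_truth_d(cfg, "ch2", c(0, 19, 20, 39, 40, 59))
  expect_equal(d, c(300, 300, 443.5, 443.5, 573.5, 573.5))

  # +20 degC linear ramp adds the CTE-mismatch drift (~1.74 um) on top
  th <- thermal_params()
  cfg_t <- experiment_config(
    activation_times_s = numeric(0),
    step_um = list(ch1 = numeric(0), ch2 = numeric(0)),
    duration_s = 100, n_samples = 8001,
    thermal = list(params = th,
                   profile = data.frame(time_s = c(0, 99),
                                        temp_C = c(25, 45))))
  d0 <- fpsense:::ground_truth_d(cfg_t, "ch2", c(0, 99))
  expect_equal(d0[2] - d0[1], 20 * temperature_sensitivity(th, 300))
  expect_equal(d0[2] - d0[1], 1.7373, tolerance = 1e-4)
})

test_that("full loop: track recovers the simulated ground truth", {
  ds <- simulate_experiment(small_config(seed = 8))
  ser <- track(ds)
  m <- dplyr::inner_join(ser, ds$ground_truth,
                         by = c("timestamp_s", "channel"))
  ok <- m$flag == "ok"
  expect_gt(mean(ok), 0.8)
  rmse <- sqrt(mean((m$d_um[ok] - m$d_true_um[ok])^2))
  expect_lt(rmse, 0.5)

  # noiseless loop is interpolation-limited (< 1 nm)
  cfg0 <- experiment_config(activation_times_s = 5,
                            step_um = list(ch1 = 130, ch2 = 130),
                            jitter_sd_pm = 0, intensity_sd = 0,
                            duration_s = 10, n_samples = 16001)
  ds0 <- simulate_experiment(cfg0)
  ser0 <- track(ds0)
  m0 <- dplyr::inner_join(ser0, ds0$ground_truth,
                          by = c("timestamp_s", "channel"))
  expect_lt(max(abs(m0$d_um - m0$d_true_um)), 1e-3)
})

test_that("translation-stage scenario calibrates to unit slope", {
  # noiseless: slope within 1e-3 of 1, intercept within 0.1 um of 0
  ds <- simulate_translation_stage(start_d_um = 300, step_um = 200,
                                   n_steps = 5, frames_per_step = 3)
  ser <- track(ds, jump_threshold_um = Inf)
  cal <- calibrate_displacement(ser, step_um = 200)
  expect_lt(abs(cal$slope - 1), 1e-3)
  expect_lt(abs(cal$intercept_um), 0.1)
  expect_equal(nrow(cal$data), 5)

  g <- glance(cal)
  expect_gt(g$r.squared, 1 - 1e-9)
  td <- tidy(cal)
  expect_equal(td$term, c("(Intercept)", "configured_um"))

  # 0 steps: a single plateau, nothing to fit
  ds0 <- simulate_translation_stage(n_steps = 0, frames_per_step = 4)
  expect_equal(nrow(detect_steps(track(ds0))), 0)

  # with 2 pm jitter the slope still holds to 1e-2
  dsj <- simulate_translation_stage(start_d_um = 300, step_um = 200,
                                    n_steps = 5, frames_per_step = 3,
                                    jitter_sd_pm = 2, seed = 5)
  calj <- calibrate_displacement(track(dsj, jump_threshold_um = Inf),
                                 step_um = 200)
  expect_lt(abs(calj$slope - 1), 1e-2)
})

test_that("plot methods return ggplot objects", {
  s <- fp_spectrum(fp_cavity(d_um = 300), n_samples = 8001)
  expect_s3_class(autoplot(s, peaks = detect_peaks(s)), "ggplot")
  ser <- staircase_series(c(300, 430), n_per = 40)
  class(ser) <- c("fp_series", class(ser))
  expect_s3_class(autoplot(ser), "ggplot")
  two <- dplyr::bind_rows(
    staircase_series(c(285, 401.5), n_per = 40, channel = "ch1"),
    staircase_series(c(300, 443.5), n_per = 40, channel = "ch2"))
  expect_s3_class(autoplot(summarize_expansion(two)), "ggplot")
})
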