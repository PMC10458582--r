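#' Configuration for a synthetic two-sensor expansion experiment
#'
#' Encodes the study conditions emulated by [simulate_experiment()]: two
#' F-P sensors with initial cavity lengths of 285 um (posterior) and
#' 300 um (anterior), three screw activations averaging 130 um each with
#' the first load split 116.5 / 143.5 um so that the anterior sensor
#' opens 27 um wider, an interrogator with 2 pm wavelength repeatability
#' at 1 Hz over 1510-1590 nm, and a 60 s quiet baseline with about one
#' minute between activations.
#'
#' @param seed Integer RNG seed; a fixed seed reproduces the dataset
#'   exactly.
#' @param initial_d_um Named numeric vector of initial cavity lengths
#'   per channel (um).
#' @param activation_times_s Activation onset times (s), strictly
#'   increasing, within the experiment duration.
#' @param step_um Named list: per channel, the step size (um) of each
#'   activation; lengths must match `activation_times_s`.
#' @param geometry An [expander_geometry()] object.
#' @param roles Named character vector mapping `anterior`/`posterior` to
#'   channel ids.
#' @param jitter_sd_pm Per-frame peak-wavelength jitter SD in pm,
#'   realized as a rigid spectral shift (interrogator repeatability).
#' @param intensity_sd Additive intensity noise SD (normalized units).
#' @param rate_hz Frame rate in Hz.
#' @param duration_s Experiment duration in seconds.
#' @param wl_range,n_samples Wavelength grid passed to the forward
#'   model.
#' @param cavity_template An [fp_cavity()] giving the optical constants
#'   (R1, R2, q, n, phi0) shared by both sensors; its `d_um` is ignored.
#' @param thermal Optional list `list(params = thermal_params(...),
#'   profile = data.frame(time_s, temp_C))` adding a linearized thermal
#'   drift to the ground truth.
#' @return An object of class `fp_experiment_config`.
#' @export
experiment_config <- function(seed = 1L,
                              initial_d_um = c(ch1 = 285, ch2 = 300),
                              activation_times_s = c(60, 120, 180),
                              step_um = list(ch1 = c(116.5, 130, 130),
                                             ch2 = c(143.5, 130, 130)),
                              geometry = expander_geometry(),
                              roles = c(anterior = "ch2",
                                        posterior = "ch1"),
                              jitter_sd_pm = 2,
                              intensity_sd = 0.001,
                              rate_hz = 1,
                              duration_s = 240,
                              wl_range = c(1510, 1590),
                              n_samples = 16001,
                              cavity_template = fp_cavity(d_um = 300),
                              thermal = NULL) {
  check_number(seed, "seed")
  check_number(jitter_sd_pm, "jitter_sd_pm", lower = 0)
  check_number(intensity_sd, "intensity_sd", lower = 0)
  check_number(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  if (is.null(names(initial_d_um)) || any(names(initial_d_um) == "")) {
    fp_abort("`initial_d_um` must be a named vector (one name per channel).",
             "fp_config_error")
  }
  channels <- names(initial_d_um)
  if (!setequal(names(step_um), channels)) {
    fp_abort("`step_um` must have one entry per channel of `initial_d_um`.",
             "fp_config_error")
  }
  n_act <- length(activation_times_s)
  if (n_act > 0 && (any(diff(activation_times_s) <= 0) ||
                    any(activation_times_s <= 0) ||
                    any(activation_times_s >= duration_s))) {
    fp_abort("`activation_times_s` must be strictly increasing and inside (0, duration_s).",
             "fp_config_error")
  }
  for (ch in channels) {
    if (length(step_um[[ch]]) != n_act) {
      fp_abort(sprintf(
        "`step_um$%s` must list one step per activation time (%d).",
        ch, n_act), "fp_config_error")
    }
    d_path <- initial_d_um[[ch]] + cumsum(c(0, step_um[[ch]]))
    if (any(d_path <= 0)) {
      fp_abort(sprintf("Schedule drives channel `%s` to a non-positive cavity length.",
                       ch), "fp_config_error")
    }
    # the grid must still resolve the fringes at the largest cavity length
    spacing <- (wl_range[2] - wl_range[1]) / (n_samples - 1)
    cav <- cavity_with_d(cavity_template, max(d_path))
    if (fsr_nm(cav, mean(wl_range)) / spacing < 10) {
      fp_abort(sprintf(
        "Schedule drives channel `%s` to d = %g um, beyond the demodulable range of the configured grid.",
        ch, max(d_path)), "fp_config_error")
    }
  }
  structure(
    list(seed = as.integer(seed), initial_d_um = initial_d_um,
         activation_times_s = activation_times_s, step_um = step_um,
         geometry = geometry, roles = roles,
         jitter_sd_pm = jitter_sd_pm, intensity_sd = intensity_sd,
         rate_hz = rate_hz, duration_s = duration_s,
         wl_range = wl_range, n_samples = n_samples,
         cavity_template = cavity_template, thermal = thermal),
    class = "fp_experiment_config"
  )
}

cavity_with_d <- function(template, d_um) {
  fp_cavity(d_um = d_um, R1 = template$R1, R2 = template$R2,
            q = template$q, n = template$n, phi0 = template$phi0)
}

#' Ground-truth cavity length over time for one channel
#'
#' Staircase of instantaneous activation steps plus optional linearized
#' thermal drift (sensitivity evaluated at the initial cavity length).
#'
#' @param config An [experiment_config()].
#' @param channel Channel id.
#' @param times_s Evaluation times (s).
#' @return Numeric vector of cavity lengths (um).
#' @keywords internal
ground_truth_d <- function(config, channel, times_s) {
  d0 <- config$initial_d_um[[channel]]
  steps <- config$step_um[[channel]]
  d <- rep(d0, length(times_s))
  for (j in seq_along(config$activation_times_s)) {
    d <- d + steps[j] * (times_s >= config$activation_times_s[j])
  }
  if (!is.null(config$thermal)) {
    prof <- config$thermal$profile
    temp <- stats::approx(prof$time_s, prof$temp_C, xout = times_s,
                          rule = 2)$y
    sens <- temperature_sensitivity(config$thermal$params, d0)
    d <- d + sens * (temp - temp[1])
  }
  d
}

#' Simulate a full two-sensor expansion experiment
#'
#' Generates a ground-truthed dataset of reflected-spectrum frames: per
#' channel, the true cavity length follows the configured activation
#' staircase (plus optional thermal drift); each frame is the forward
#' two-beam spectrum of that cavity, rigidly shifted in wavelength by a
#' per-frame jitter draw (emulating interrogator peak-wavelength
#' repeatability) with additive intensity noise. The output is
#' deterministic for a fixed config seed.
#'
#' @param config An [experiment_config()].
#' @return An object of class `fp_experiment`: a list with `frames`
#'   (named list per channel of `fp_spectrum` frames), `ground_truth`
#'   (tibble `timestamp_s`, `channel`, `d_true_um`) and `config`.
#' @examples
#' cfg <- experiment_config(duration_s = 20, activation_times_s = 10,
#'                          step_um = list(ch1 = 130, ch2 = 130))
#' ds <- simulate_experiment(cfg)
#' names(ds$frames)
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "fp_experiment_config"))
  withr::with_seed(config$seed, {
    times <- seq(0, config$duration_s - 1 / config$rate_hz,
                 by = 1 / config$rate_hz)
    channels <- names(config$initial_d_um)
    wl <- seq(config$wl_range[1], config$wl_range[2],
              length.out = config$n_samples)
    gt <- list()
    frames <- list()
    for (ch in channels) {
      d_true <- ground_truth_d(config, ch, times)
      shifts_nm <- stats::rnorm(length(times),
                                sd = config$jitter_sd_pm / 1e3)
      frames[[ch]] <- purrr::map(seq_along(times), function(i) {
        cav <- cavity_with_d(config$cavity_template, d_true[i])
        # a rigid spectral shift by +s moves every peak by +s
        intensity <- fp_reflectance(wl - shifts_nm[i], cav)
        if (config$intensity_sd > 0) {
          intensity <- intensity +
            stats::rnorm(length(wl), sd = config$intensity_sd)
        }
        new_fp_spectrum(wl, intensity, timestamp_s = times[i],
                        channel = ch)
      })
      gt[[ch]] <- tibble::tibble(timestamp_s = times, channel = ch,
                                 d_true_um = d_true)
    }
    structure(
      list(frames = frames, ground_truth = dplyr::bind_rows(gt),
           config = config),
      class = "fp_experiment"
    )
  })
}

#' @export
print.fp_experiment <- function(x, ...) {
  nch <- length(x$frames)
  nfr <- if (nch) length(x$frames[[1]]) else 0
  cat(sprintf("<fp_experiment> %d channel(s) x %d frame(s), %d-sample grid %g-%g nm\n",
              nch, nfr, x$config$n_samples, x$config$wl_range[1],
              x$config$wl_range[2]))
  invisible(x)
}

#' Simulate a translation-stage calibration run
#'
#' Reproduces the bench validation scenario: the cavity length is
#' stepped from `start_d_um` in `n_steps` equal increments of `step_um`
#' (a precision translation stage), holding each plateau for
#' `frames_per_step` frames. Demodulating the frames and regressing the
#' measured displacement on the configured displacement should give unit
#' slope and zero intercept; see [calibrate_displacement()].
#'
#' @param start_d_um Initial cavity length (um).
#' @param step_um Stage increment per step (um, > 0).
#' @param n_steps Number of increments (>= 0).
#' @param frames_per_step Frames recorded on each plateau.
#' @param seed RNG seed.
#' @param jitter_sd_pm,intensity_sd Noise settings as in
#'   [experiment_config()]; both default to 0 (noiseless bench test).
#' @param wl_range,n_samples,cavity_template Forward-model settings as
#'   in [experiment_config()].
#' @return An `fp_experiment` with a single channel `"stage"`.
#' @examples
#' ds <- simulate_translation_stage(n_steps = 2, frames_per_step = 2)
#' @export
simulate_translation_stage <- function(start_d_um = 300, step_um = 200,
                                       n_steps = 5, frames_per_step = 5,
                                       seed = 1L, jitter_sd_pm = 0,
                                       intensity_sd = 0,
                                       wl_range = c(1510, 1590),
                                       n_samples = 16001,
                                       cavity_template = fp_cavity(d_um = 300)) {
  check_number(start_d_um, "start_d_um", lower = 0, strict_lower = TRUE)
  check_number(step_um, "step_um", lower = 0, strict_lower = TRUE)
  check_number(n_steps, "n_steps", lower = 0)
  check_number(frames_per_step, "frames_per_step", lower = 1)
  d_levels <- start_d_um + step_um * (0:n_steps)
  n_frames <- length(d_levels) * frames_per_step
  times <- seq_len(n_frames) - 1
  d_true <- rep(d_levels, each = frames_per_step)
  wl <- seq(wl_range[1], wl_range[2], length.out = n_samples)
  withr::with_seed(as.integer(seed), {
    shifts_nm <- stats::rnorm(n_frames, sd = jitter_sd_pm / 1e3)
    frames <- purrr::map(seq_len(n_frames), function(i) {
      cav <- cavity_with_d(cavity_template, d_true[i])
      intensity <- fp_reflectance(wl - shifts_nm[i], cav)
      if (intensity_sd > 0) {
        intensity <- intensity + stats::rnorm(length(wl), sd = intensity_sd)
      }
      new_fp_spectrum(wl, intensity, timestamp_s = times[i],
                      channel = "stage")
    })
    structure(
      list(frames = list(stage = frames),
           ground_truth = tibble::tibble(timestamp_s = times,
                                         channel = "stage",
                                         d_true_um = d_true),
           config = list(start_d_um = start_d_um, step_um = step_um,
                         n_steps = n_steps,
                         frames_per_step = frames_per_step,
                         seed = as.integer(seed),
                         jitter_sd_pm = jitter_sd_pm,
                         intensity_sd = intensity_sd,
                         wl_range = wl_range, n_samples = n_samples)),
      class = "fp_experiment"
    )
  })
}

#' Fit the measured-vs-configured displacement line of a stage run
#'
#' Detects the plateaus of a tracked translation-stage series, forms the
#' cumulative measured displacement at each stage position and regresses
#' it on the configured displacement. A well-calibrated sensor gives
#' slope 1 and intercept 0.
#'
#' @param series An `fp_series` from tracking a
#'   [simulate_translation_stage()] dataset (single channel).
#' @param step_um Configured stage increment (um).
#' @param min_step_um Passed to [detect_steps()]; defaults to half the
#'   configured increment.
#' @param plateau_window_s Passed to [detect_steps()].
#' @return An object of class `fp_calibration` wrapping the linear fit;
#'   see [tidy.fp_calibration()] and [glance.fp_calibration()].
#' @export
calibrate_displacement <- function(series, step_um,
                                   min_step_um = step_um / 2,
                                   plateau_window_s = 30) {
  check_number(step_um, "step_um", lower = 0, strict_lower = TRUE)
  steps <- detect_steps(series, min_step_um = min_step_um,
                        plateau_window_s = plateau_window_s)
  if (nrow(steps) < 2) {
    fp_abort("Need at least 2 detected stage steps to fit a calibration line.",
             "fp_invalid_input")
  }
  data <- tibble::tibble(
    configured_um = step_um * steps$index,
    measured_um = steps$cumulative_um
  )
  fit <- stats::lm(measured_um ~ configured_um, data = data)
  structure(
    list(fit = fit, data = data,
         slope = unname(stats::coef(fit)[2]),
         intercept_um = unname(stats::coef(fit)[1])),
    class = "fp_calibration"
  )
}

#' @export
print.fp_calibration <- function(x, ...) {
  cat(sprintf(
    "<fp_calibration> measured = %.6f x configured %+.4g um (n = %d)\n",
    x$slope, x$intercept_um, nrow(x$data)))
  invisible(x)
}

#' Tidy the coefficients of a displacement calibration fit
#'
#' @param x An `fp_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy fp_calibration
#' @export
tidy.fp_calibration <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], statistic = co[, 3],
                 p.value = co[, 4])
}

#' One-row overview of a displacement calibration fit
#'
#' @param x An `fp_calibration`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept_um`, `r.squared`,
#'   `sigma_um`, `n`.
#' @method glance fp_calibration
#' @export
glance.fp_calibration <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(slope = x$slope, intercept_um = x$intercept_um,
                 r.squared = s$r.squared, sigma_um = s$sigma,
                 n = nrow(x$data))
}
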