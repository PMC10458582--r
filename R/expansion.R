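#' Expected screw-driven expansion
#'
#' Displacement produced by turning the expansion screw: pitch times the
#' number of turns. With the default geometry (0.8 mm per turn, 1/6 turn
#' per activation) each activation is expected to open the suture by
#' about 0.13 mm and a total of 1/2 turn by 0.4 mm.
#'
#' @param turns Number of screw turns (>= 0); may be fractional.
#' @param geometry An [expander_geometry()] object.
#' @return Expected displacement in mm.
#' @examples
#' expected_expansion(1 / 6, expander_geometry())
#' @export
expected_expansion <- function(turns, geometry = expander_geometry()) {
  stopifnot(inherits(geometry, "fp_geometry"))
  if (!is.numeric(turns) || any(!is.finite(turns)) || any(turns < 0)) {
    fp_abort("`turns` must be non-negative.", "fp_invalid_input")
  }
  geometry$pitch_mm_per_turn * turns
}

#' Midpalatal-suture expansion angle from two opening displacements
#'
#' Under the rigid-wedge, left-right-symmetric small-angle model the
#' suture opening angle is the difference between the anterior and
#' posterior opening displacements divided by the sensor separation:
#' \deqn{\theta = \frac{\Delta_{ant} - \Delta_{post}}{s}.}
#' Positive angles mean the suture opens wider anteriorly (V-type
#' expansion, apex posterior); zero means parallel expansion.
#'
#' @param delta_anterior_um,delta_posterior_um Opening displacements at
#'   the anterior and posterior sensor, in micrometres (vectorized).
#' @param separation_um Sensor separation in micrometres (> 0).
#' @return Angle(s) in radians.
#' @examples
#' expansion_angle(27, 0, 900)   # 0.03 rad
#' @export
expansion_angle <- function(delta_anterior_um, delta_posterior_um,
                            separation_um) {
  check_number(separation_um, "separation_um", lower = 0,
               strict_lower = TRUE)
  (delta_anterior_um - delta_posterior_um) / separation_um
}

#' Convert radians to degrees
#'
#' @param theta_rad Angle(s) in radians.
#' @return Angle(s) in degrees.
#' @examples
#' rad_to_deg(0.03)  # ~1.72
#' @export
rad_to_deg <- function(theta_rad) {
  theta_rad * 180 / pi
}

#' Detect activation steps in a cavity-length time series
#'
#' Segments a (single-channel) demodulated series into plateaus
#' separated by abrupt steps. A step boundary is any frame-to-frame
#' change exceeding `min_step_um`; consecutive boundary samples are
#' merged into one transition. Each step's size is the difference of
#' robust plateau medians taken over `plateau_window_s` before and after
#' the transition, and its onset is the first sample beyond the
#' pre-step plateau.
#'
#' @param series An `fp_series` tibble (columns `timestamp_s`, `d_um`,
#'   optionally `channel` and `flag`). Multi-channel input is split by
#'   channel and results are row-bound.
#' @param min_step_um Minimum frame-to-frame change treated as a step
#'   (um).
#' @param plateau_window_s Length of the plateau windows used for the
#'   step medians, in seconds.
#' @return A tibble with one row per detected step: `channel`, `index`,
#'   `onset_s`, `delta_um`, `cumulative_um`, `pre_median_um`,
#'   `post_median_um`. Zero rows when no step is found.
#' @examples
#' s <- tibble::tibble(timestamp_s = 0:59,
#'                     d_um = rep(c(300, 430), each = 30),
#'                     channel = "ch1")
#' detect_steps(s)
#' @export
detect_steps <- function(series, min_step_um = 50, plateau_window_s = 30) {
  series <- validate_series(series)
  chans <- unique(series$channel)
  if (length(chans) > 1) {
    out <- purrr::map(chans, function(ch) {
      detect_steps(series[series$channel == ch, , drop = FALSE],
                   min_step_um = min_step_um,
                   plateau_window_s = plateau_window_s)
    })
    return(dplyr::bind_rows(out))
  }
  ok <- is.na(series$flag) | series$flag %in% c("ok", "suspect_jump")
  s <- series[ok & is.finite(series$d_um), , drop = FALSE]
  empty <- tibble::tibble(channel = character(), index = integer(),
                          onset_s = numeric(), delta_um = numeric(),
                          cumulative_um = numeric(),
                          pre_median_um = numeric(),
                          post_median_um = numeric())
  if (nrow(s) < 4) return(empty)
  t <- s$timestamp_s
  d <- s$d_um
  jump <- which(abs(diff(d)) > min_step_um)
  if (length(jump) == 0) return(empty)
  # merge consecutive boundary samples into single transitions
  grp <- cumsum(c(TRUE, diff(jump) > 1))
  trans <- split(jump, grp)
  i0s <- purrr::map_int(trans, ~ as.integer(min(.x)))      # last pre sample
  i1s <- purrr::map_int(trans, ~ as.integer(max(.x)) + 1L) # first post sample
  rows <- purrr::map(seq_along(trans), function(g) {
    i0 <- i0s[g]
    i1 <- i1s[g]
    # plateau windows are clipped at the neighbouring transitions so
    # that closely spaced steps keep their plateaus disjoint
    pre_lo <- if (g > 1) i1s[g - 1L] else 1L
    post_hi <- if (g < length(trans)) i0s[g + 1L] else length(d)
    pre <- d[pre_lo:i0][t[pre_lo:i0] >= t[i0] - plateau_window_s]
    post <- d[i1:post_hi][t[i1:post_hi] <= t[i1] + plateau_window_s]
    tibble::tibble(
      channel = s$channel[1],
      onset_s = t[i0 + 1L],
      delta_um = stats::median(post) - stats::median(pre),
      pre_median_um = stats::median(pre),
      post_median_um = stats::median(post)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[abs(out$delta_um) >= min_step_um, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$index <- seq_len(nrow(out))
  out$cumulative_um <- cumsum(out$delta_um)
  dplyr::select(out, "channel", "index", "onset_s", "delta_um",
                "cumulative_um", "pre_median_um", "post_median_um")
}

validate_series <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("timestamp_s", "d_um") %in% names(series))) {
    fp_abort("`series` must have columns `timestamp_s` and `d_um`.",
             "fp_invalid_input")
  }
  series <- tibble::as_tibble(series)
  if (!"channel" %in% names(series)) series$channel <- "ch1"
  if (!"flag" %in% names(series)) series$flag <- "ok"
  for (ch in unique(series$channel)) {
    ts <- series$timestamp_s[series$channel == ch]
    if (any(diff(ts) <= 0)) {
      fp_abort(sprintf(
        "Timestamps must be strictly increasing within channel `%s`.", ch),
        "fp_invalid_input")
    }
  }
  series
}

#' Baseline noise of a cavity-length series
#'
#' Sample standard deviation of the demodulated cavity length over a
#' quiet time window — the sensor's effective displacement resolution.
#' The window must lie within a single plateau: if it contains a step
#' larger than `step_guard_um` an invalid-window error is raised.
#'
#' @param series An `fp_series` tibble (single channel).
#' @param window Time window `c(t0, t1)` in seconds; default the whole
#'   series.
#' @param step_guard_um Any frame-to-frame change above this value marks
#'   the window as spanning a step (um).
#' @param min_samples Minimum number of unflagged samples required.
#' @return Standard deviation of `d_um` over the window, in um.
#' @examples
#' s <- tibble::tibble(timestamp_s = 0:59, d_um = rnorm(60, 300, 0.5))
#' baseline_noise(s)
#' @export
baseline_noise <- function(series, window = NULL, step_guard_um = 10,
                           min_samples = 10) {
  series <- validate_series(series)
  if (length(unique(series$channel)) > 1) {
    fp_abort("`baseline_noise()` expects a single-channel series.",
             "fp_invalid_input")
  }
  if (is.null(window)) {
    window <- range(series$timestamp_s)
  }
  ok <- is.na(series$flag) | series$flag == "ok"
  sel <- ok & is.finite(series$d_um) &
    series$timestamp_s >= window[1] & series$timestamp_s <= window[2]
  d <- series$d_um[sel]
  if (length(d) < min_samples) {
    fp_abort(sprintf(
      "Window contains %d usable samples; at least %d required.",
      length(d), min_samples), "fp_invalid_input")
  }
  if (max(abs(diff(d))) > step_guard_um) {
    fp_abort("Window spans an activation step; choose a window inside a single plateau.",
             "fp_invalid_window")
  }
  stats::sd(d)
}

#' Summarize a two-sensor expansion experiment
#'
#' Aligns the detected activation steps of the two sensors to the
#' activation schedule and derives the experiment-level outputs: per
#' activation the anterior and posterior displacements, their average,
#' the expected screw-driven displacement, the cumulative
#' anterior-posterior difference and the suture opening angle; plus the
#' mean and SD of (average - expected) and the pre-activation baseline
#' noise per channel.
#'
#' @param series A two-channel `fp_series` tibble (long format).
#' @param geometry An [expander_geometry()] object.
#' @param roles Named character vector mapping wedge positions to
#'   channel ids, e.g. `c(anterior = "ch2", posterior = "ch1")`. The
#'   mapping is a required experimental fact and is never inferred from
#'   the data.
#' @param schedule Turn fraction per activation; either a numeric vector
#'   (one element per expected activation) or `NULL` to use the
#'   geometry's `activation_fraction` for every detected step.
#' @param min_step_um,plateau_window_s Passed to [detect_steps()].
#' @return An object of class `expansion_summary`; see
#'   [tidy.expansion_summary()] and [glance.expansion_summary()].
#' @export
summarize_expansion <- function(series, geometry = expander_geometry(),
                                roles = c(anterior = "ch2",
                                          posterior = "ch1"),
                                schedule = NULL, min_step_um = 50,
                                plateau_window_s = 30) {
  stopifnot(inherits(geometry, "fp_geometry"))
  series <- validate_series(series)
  if (!all(c("anterior", "posterior") %in% names(roles))) {
    fp_abort("`roles` must name both `anterior` and `posterior` channels.",
             "fp_invalid_input")
  }
  chans <- unique(series$channel)
  missing <- setdiff(unname(roles[c("anterior", "posterior")]), chans)
  if (length(missing) > 0) {
    fp_abort(sprintf("Channel(s) %s not present in `series`.",
                     paste(missing, collapse = ", ")),
             "fp_invalid_input")
  }
  steps <- detect_steps(series, min_step_um = min_step_um,
                        plateau_window_s = plateau_window_s)
  ant <- steps[steps$channel == roles[["anterior"]], , drop = FALSE]
  post <- steps[steps$channel == roles[["posterior"]], , drop = FALSE]
  if (nrow(ant) != nrow(post)) {
    fp_abort(sprintf(
      "Step count mismatch between channels: anterior %d vs posterior %d.",
      nrow(ant), nrow(post)), "fp_reconciliation_error")
  }
  n_act <- nrow(ant)
  if (is.null(schedule)) {
    schedule <- rep(geometry$activation_fraction, n_act)
  }
  if (n_act != length(schedule)) {
    fp_abort(sprintf(
      "Detected %d activation step(s) per channel but the schedule lists %d; unmatched activations: %s.",
      n_act, length(schedule),
      paste(seq(min(n_act, length(schedule)) + 1,
                max(n_act, length(schedule))), collapse = ", ")),
      "fp_reconciliation_error")
  }
  expected_um <- expected_expansion(schedule, geometry) * 1e3
  activations <- tibble::tibble(
    activation = seq_len(n_act),
    onset_s = (ant$onset_s + post$onset_s) / 2,
    anterior_um = ant$delta_um,
    posterior_um = post$delta_um,
    average_um = (ant$delta_um + post$delta_um) / 2,
    expected_um = expected_um,
    error_um = (ant$delta_um + post$delta_um) / 2 - expected_um,
    diff_cum_um = cumsum(ant$delta_um - post$delta_um),
    theta_rad = expansion_angle(cumsum(ant$delta_um),
                                cumsum(post$delta_um),
                                geometry$separation_um)
  )
  activations$theta_deg <- rad_to_deg(activations$theta_rad)

  baseline <- purrr::map_dbl(
    stats::setNames(unname(roles[c("anterior", "posterior")]),
                    c("anterior", "posterior")),
    function(ch) {
      sub <- series[series$channel == ch, , drop = FALSE]
      t_first <- if (n_act > 0) {
        min(steps$onset_s[steps$channel == ch])
      } else {
        max(sub$timestamp_s) + 1
      }
      win <- c(min(sub$timestamp_s), t_first - 1)
      tryCatch(baseline_noise(sub, window = win), error = function(e) NA_real_)
    })

  structure(
    list(
      activations = activations,
      error_mean_um = mean(activations$error_um),
      error_sd_um = stats::sd(activations$error_um),
      baseline_sd_um = baseline,
      geometry = geometry,
      roles = roles,
      schedule = schedule
    ),
    class = "expansion_summary"
  )
}

#' @export
print.expansion_summary <- function(x, ...) {
  cat("Expansion summary -", nrow(x$activations), "activation(s)\n")
  cat(sprintf("  roles: anterior = %s, posterior = %s (separation %g um)\n",
              x$roles[["anterior"]], x$roles[["posterior"]],
              x$geometry$separation_um))
  print(as.data.frame(x$activations), digits = 4)
  cat(sprintf("  average - expected: %.3g +/- %.3g um (mean +/- SD)\n",
              x$error_mean_um, x$error_sd_um))
  cat(sprintf("  baseline SD: anterior %.3g um, posterior %.3g um\n",
              x$baseline_sd_um[["anterior"]],
              x$baseline_sd_um[["posterior"]]))
  invisible(x)
}

#' Tidy the per-activation table of an expansion summary
#'
#' @param x An `expansion_summary`.
#' @param ... Unused.
#' @return The per-activation tibble: displacements, average, expected,
#'   error, cumulative anterior-posterior difference and opening angle.
#' @method tidy expansion_summary
#' @export
tidy.expansion_summary <- function(x, ...) {
  x$activations
}

#' One-row overview of an expansion summary
#'
#' @param x An `expansion_summary`.
#' @param ... Unused.
#' @return A one-row tibble: activation count, total average and
#'   expected displacement, (average - expected) mean and SD, final
#'   opening angle, baseline SDs.
#' @method glance expansion_summary
#' @export
glance.expansion_summary <- function(x, ...) {
  a <- x$activations
  tibble::tibble(
    n_activations = nrow(a),
    total_average_um = sum(a$average_um),
    total_expected_um = sum(a$expected_um),
    error_mean_um = x$error_mean_um,
    error_sd_um = x$error_sd_um,
    theta_final_rad = if (nrow(a)) a$theta_rad[nrow(a)] else NA_real_,
    theta_final_deg = if (nrow(a)) a$theta_deg[nrow(a)] else NA_real_,
    baseline_sd_anterior_um = x$baseline_sd_um[["anterior"]],
    baseline_sd_posterior_um = x$baseline_sd_um[["posterior"]]
  )
}
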