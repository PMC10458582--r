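#' Interference phase of the two-beam F-P cavity
#'
#' The phase difference between the beam reflected at the fiber end face
#' and the beam reflected at the opposing reflector is
#' \deqn{\delta(\lambda) = \frac{4 \pi n d}{\lambda} + \varphi_0,}
#' i.e. a double pass of the gap plus an additional phase. For fixed
#' cavity parameters the phase decreases strictly with wavelength.
#'
#' @param wavelength_nm Wavelength(s) in nm; must be positive.
#' @param cavity An [fp_cavity()] object.
#' @return Phase in radians, same length as `wavelength_nm`.
#' @examples
#' fp_phase(1550, fp_cavity(d_um = 300))
#' @export
fp_phase <- function(wavelength_nm, cavity) {
  stopifnot(inherits(cavity, "fp_cavity"))
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) == 0L ||
      any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0)) {
    fp_abort("`wavelength_nm` must be positive and finite.",
             "fp_invalid_input")
  }
  d_nm <- cavity$d_um * 1e3
  4 * pi * cavity$n * d_nm / wavelength_nm + cavity$phi0
}

#' Normalized reflected intensity of the two-beam F-P cavity
#'
#' Two-beam interference reflectance of a low-finesse cavity,
#' \deqn{\frac{I_r}{I_i} = \frac{R_1 + q^2 R_2 - 2 q \sqrt{R_1 R_2} \cos\delta}
#'                              {1 + q^2 R_1 R_2 - 2 q \sqrt{R_1 R_2} \cos\delta},}
#' with \eqn{\delta} from [fp_phase()]. The expression is monotone
#' decreasing in \eqn{\cos\delta}, so reflected maxima sit exactly at odd
#' multiples of \eqn{\pi} and minima at even multiples.
#'
#' @inheritParams fp_phase
#' @return Normalized intensity Ir/Ii in `[0, 1]`, same length as
#'   `wavelength_nm`.
#' @examples
#' cav <- fp_cavity(d_um = 300)
#' fp_reflectance(c(1510, 1550, 1590), cav)
#' @export
fp_reflectance <- function(wavelength_nm, cavity) {
  delta <- fp_phase(wavelength_nm, cavity)
  fp_reflectance_phase(delta, cavity)
}

# reflectance as a function of phase; shared by the wavelength route
fp_reflectance_phase <- function(delta, cavity) {
  b <- 2 * cavity$q * sqrt(cavity$R1 * cavity$R2)
  cd <- cos(delta)
  (cavity$R1 + cavity$q^2 * cavity$R2 - b * cd) /
    (1 + cavity$q^2 * cavity$R1 * cavity$R2 - b * cd)
}

new_fp_spectrum <- function(wavelength_nm, intensity,
                            timestamp_s = NA_real_,
                            channel = NA_character_) {
  out <- tibble::tibble(wavelength_nm = wavelength_nm,
                        intensity = intensity)
  class(out) <- c("fp_spectrum", class(out))
  attr(out, "timestamp_s") <- timestamp_s
  attr(out, "channel") <- channel
  out
}

#' Coerce a data frame to a reflection spectrum
#'
#' Validates and tags a two-column data frame (`wavelength_nm`,
#' `intensity`) as an `fp_spectrum`: wavelengths strictly increasing,
#' intensities finite and non-negative.
#'
#' @param x A data frame with numeric columns `wavelength_nm` and
#'   `intensity`.
#' @param timestamp_s Acquisition time in seconds (optional).
#' @param channel Sensor/channel identifier (optional).
#' @return A tibble of class `fp_spectrum`.
#' @export
as_fp_spectrum <- function(x, timestamp_s = NA_real_,
                           channel = NA_character_) {
  if (!is.data.frame(x) ||
      !all(c("wavelength_nm", "intensity") %in% names(x))) {
    fp_abort("Need a data frame with columns `wavelength_nm` and `intensity`.",
             "fp_format_error")
  }
  wl <- x$wavelength_nm
  it <- x$intensity
  if (!is.numeric(wl) || !is.numeric(it)) {
    fp_abort("Spectrum columns must be numeric.", "fp_format_error")
  }
  bad <- which(!is.finite(wl) | !is.finite(it) | it < 0)
  if (length(bad) > 0) {
    fp_abort(sprintf(
      "Non-finite or negative spectrum values (first offending row: %d).",
      bad[1]), "fp_format_error")
  }
  nonmono <- which(diff(wl) <= 0)
  if (length(nonmono) > 0) {
    fp_abort(sprintf(
      "Wavelengths must be strictly increasing (violated at row %d).",
      nonmono[1] + 1L), "fp_format_error")
  }
  new_fp_spectrum(wl, it, timestamp_s = timestamp_s, channel = channel)
}

#' Generate a sampled reflection spectrum
#'
#' Evaluates the two-beam reflectance on a uniform wavelength grid. The
#' grid must resolve the interference fringes: the local free spectral
#' range is about \eqn{\lambda^2 / (2 n d)}, and fewer than
#' `min_samples_per_fringe` samples per fringe triggers a warning (or an
#' error with `check = "error"`). The default grid spans the 1510-1590 nm
#' window of a telecom interrogator at 5 pm spacing, fine enough for
#' pm-level peak interpolation.
#'
#' @param cavity An [fp_cavity()] object.
#' @param wl_range Wavelength span `c(min, max)` in nm.
#' @param n_samples Number of grid samples (>= 3).
#' @param timestamp_s,channel Optional frame metadata.
#' @param check One of `"warn"`, `"error"`, `"none"`: what to do when the
#'   grid is too coarse to resolve the fringes.
#' @param min_samples_per_fringe Resolvability threshold (default 10).
#' @return A tibble of class `fp_spectrum` with columns `wavelength_nm`
#'   and `intensity`.
#' @examples
#' s <- fp_spectrum(fp_cavity(d_um = 300))
#' nrow(s)
#' @export
fp_spectrum <- function(cavity, wl_range = c(1510, 1590),
                        n_samples = 16001, timestamp_s = NA_real_,
                        channel = NA_character_,
                        check = c("warn", "error", "none"),
                        min_samples_per_fringe = 10) {
  stopifnot(inherits(cavity, "fp_cavity"))
  check <- match.arg(check)
  if (length(wl_range) != 2L || !all(is.finite(wl_range)) ||
      wl_range[1] <= 0 || wl_range[2] <= wl_range[1]) {
    fp_abort("`wl_range` must be positive, increasing bounds.",
             "fp_invalid_input")
  }
  if (n_samples < 3) {
    fp_abort("`n_samples` must be at least 3.", "fp_invalid_input")
  }
  wl <- seq(wl_range[1], wl_range[2], length.out = n_samples)
  spacing <- (wl_range[2] - wl_range[1]) / (n_samples - 1)
  fsr <- fsr_nm(cavity, mean(wl_range))
  spf <- fsr / spacing
  if (check != "none" && spf < min_samples_per_fringe) {
    msg <- sprintf(
      "Grid too coarse: %.1f samples per ~%.3g nm fringe (need >= %g).",
      spf, fsr, min_samples_per_fringe)
    if (check == "error") fp_abort(msg, "fp_grid_error")
    rlang::warn(msg, class = "fp_grid_warning")
  }
  new_fp_spectrum(wl, fp_reflectance(wl, cavity),
                  timestamp_s = timestamp_s, channel = channel)
}

#' Local free spectral range
#'
#' Approximate wavelength spacing of adjacent interference maxima near a
#' given wavelength: \eqn{\mathrm{FSR} \approx \lambda^2 / (2 n d)}.
#'
#' @inheritParams fp_phase
#' @return FSR in nm.
#' @examples
#' fsr_nm(fp_cavity(d_um = 300), 1550)
#' @export
fsr_nm <- function(cavity, wavelength_nm = 1550) {
  stopifnot(inherits(cavity, "fp_cavity"))
  wavelength_nm^2 / (2 * cavity$n * cavity$d_um * 1e3)
}

#' Analytic resonance (interference-maximum) wavelengths
#'
#' Closed-form wavelengths at which the reflected intensity is maximal:
#' solutions of \eqn{\delta(\lambda) = (2k+1)\pi} for integer fringe
#' order \eqn{k \ge 0} within the span. With `phi0 = 0` these are
#' \eqn{\lambda = 4 n d / (2k+1)}.
#'
#' @param cavity An [fp_cavity()] object.
#' @param wl_range Wavelength span `c(min, max)` in nm.
#' @return A tibble with columns `k` (fringe order, descending as
#'   wavelength increases) and `wavelength_nm` (ascending).
#' @examples
#' resonance_wavelengths(fp_cavity(d_um = 300))
#' @export
resonance_wavelengths <- function(cavity, wl_range = c(1510, 1590)) {
  stopifnot(inherits(cavity, "fp_cavity"))
  u <- 4 * pi * cavity$n * cavity$d_um * 1e3   # nm * rad
  # delta = u/lambda + phi0 = (2k+1)*pi  =>  lambda = u / ((2k+1)*pi - phi0)
  phase_lo <- u / wl_range[2] + cavity$phi0
  phase_hi <- u / wl_range[1] + cavity$phi0
  k_lo <- ceiling((phase_lo / pi - 1) / 2)
  k_hi <- floor((phase_hi / pi - 1) / 2)
  k <- seq(max(0, k_lo), k_hi)
  if (length(k) == 0 || k_hi < k_lo) {
    return(tibble::tibble(k = integer(), wavelength_nm = numeric()))
  }
  lam <- u / ((2 * k + 1) * pi - cavity$phi0)
  keep <- lam >= wl_range[1] & lam <= wl_range[2]
  tibble::tibble(k = as.integer(rev(k[keep])),
                 wavelength_nm = rev(lam[keep]))
}

#' Cavity-length temperature sensitivity of a mounted sensor
#'
#' The mount expands over the full gauge length `l` with CTE
#' \eqn{\alpha_1} while the fiber occupies `l - d` of it with CTE
#' \eqn{\alpha_2}; the gap therefore changes with temperature as
#' \deqn{\frac{\Delta d}{\Delta T} = l\,\alpha_1 - (l - d)\,\alpha_2.}
#'
#' @param thermal A [thermal_params()] object.
#' @param d_um Cavity length in micrometres; must be smaller than the
#'   gauge length.
#' @return Sensitivity in micrometres per degree Celsius.
#' @examples
#' temperature_sensitivity(thermal_params(6, 15e-6, 5.5e-7), 300)
#' @export
temperature_sensitivity <- function(thermal, d_um) {
  stopifnot(inherits(thermal, "fp_thermal"))
  check_number(d_um, "d_um", lower = 0)
  d_mm <- d_um / 1e3
  if (d_mm >= thermal$l_mm) {
    fp_abort(sprintf(
      "Cavity length (%g mm) must be smaller than the gauge length (%g mm).",
      d_mm, thermal$l_mm), "fp_invalid_geometry")
  }
  sens_mm <- thermal$l_mm * thermal$alpha1_per_C -
    (thermal$l_mm - d_mm) * thermal$alpha2_per_C
  sens_mm * 1e3
}

#' Apply a linearized temperature drift to a cavity length
#'
#' Shifts a cavity length by `sensitivity * dT`, with the sensitivity
#' either computed from the thermal model at the initial cavity length or
#' supplied directly (e.g. an empirically fitted value).
#'
#' @param d0_um Initial cavity length in micrometres.
#' @param dT_C Temperature change(s) in degrees Celsius.
#' @param thermal A [thermal_params()] object (ignored when
#'   `sensitivity_um_per_C` is given).
#' @param sensitivity_um_per_C Optional empirical sensitivity overriding
#'   the model value.
#' @return Cavity length(s) in micrometres, same length as `dT_C`.
#' @examples
#' apply_temperature(300, 20, thermal_params())
#' apply_temperature(300, 20, sensitivity_um_per_C = 0.1081)
#' @export
apply_temperature <- function(d0_um, dT_C, thermal = thermal_params(),
                              sensitivity_um_per_C = NULL) {
  check_number(d0_um, "d0_um", lower = 0, strict_lower = TRUE)
  if (!is.numeric(dT_C) || any(!is.finite(dT_C))) {
    fp_abort("`dT_C` must be finite.", "fp_invalid_input")
  }
  s <- if (is.null(sensitivity_um_per_C)) {
    temperature_sensitivity(thermal, d0_um)
  } else {
    check_number(sensitivity_um_per_C, "sensitivity_um_per_C")
  }
  d0_um + s * dT_C
}
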