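#' @keywords internal
fp_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "fpsense_error"), ...)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fp_abort(sprintf("`%s` must be a single finite number.", name),
             "fp_invalid_input")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    fp_abort(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), "fp_invalid_input")
  }
  invisible(x)
}

#' Fabry-Perot cavity parameters
#'
#' Physical state of one low-finesse fiber-optic F-P sensor: the cleaved
#' fiber end face (reflectivity `R1`) and the mirrored reflector
#' (reflectivity `R2`) separated by a gap of physical length `d_um` filled
#' with a medium of refractive index `n`. `q` is the light coupling
#' coefficient of the reflector beam back into the lead-in fiber and
#' `phi0` an additional interferometric phase.
#'
#' Defaults correspond to a cleaved silica end face (`R1 = 0.04`), a
#' high-reflectivity coated reflector (`R2 = 0.99`), an air gap
#' (`n = 1`), ideal coupling (`q = 1`) and no extra phase (`phi0 = 0`).
#'
#' @param d_um Physical cavity length in micrometres; must be positive.
#' @param R1,R2 Surface reflectivities in `[0, 1]`.
#' @param q Light coupling coefficient in `(0, 1]`.
#' @param n Refractive index of the cavity medium (>= 1).
#' @param phi0 Additional phase offset in radians.
#' @return An object of class `fp_cavity`.
#' @examples
#' cav <- fp_cavity(d_um = 300)
#' fp_reflectance(1550, cav)
#' @export
fp_cavity <- function(d_um, R1 = 0.04, R2 = 0.99, q = 1, n = 1, phi0 = 0) {
  check_number(d_um, "d_um", lower = 0, strict_lower = TRUE)
  check_number(R1, "R1", 0, 1)
  check_number(R2, "R2", 0, 1)
  check_number(q, "q", 0, 1, strict_lower = TRUE)
  check_number(n, "n", lower = 1)
  check_number(phi0, "phi0")
  structure(
    list(d_um = d_um, R1 = R1, R2 = R2, q = q, n = n, phi0 = phi0),
    class = "fp_cavity"
  )
}

#' @export
print.fp_cavity <- function(x, ...) {
  cat(sprintf(
    "<fp_cavity> d = %g um, R1 = %g, R2 = %g, q = %g, n = %g, phi0 = %g rad\n",
    x$d_um, x$R1, x$R2, x$q, x$n, x$phi0
  ))
  invisible(x)
}

#' Thermal-expansion parameters of a mounted sensor
#'
#' The sensor is bonded over a fixed gauge length `l_mm`; the mount
#' (expander) material has linear thermal-expansion coefficient
#' `alpha1_per_C` and the fiber `alpha2_per_C`. Mismatch between the two
#' drives the cavity-length temperature sensitivity (see
#' [temperature_sensitivity()]).
#'
#' @param l_mm Fixed (gauge) length of the sensor mounting in mm (> 0).
#' @param alpha1_per_C Expander-material CTE, per degree Celsius (>= 0).
#' @param alpha2_per_C Fiber CTE, per degree Celsius (>= 0).
#' @return An object of class `fp_thermal`.
#' @examples
#' thermal_params(6, 15e-6, 5.5e-7)
#' @export
thermal_params <- function(l_mm = 6, alpha1_per_C = 15e-6,
                           alpha2_per_C = 5.5e-7) {
  check_number(l_mm, "l_mm", lower = 0, strict_lower = TRUE)
  check_number(alpha1_per_C, "alpha1_per_C", lower = 0)
  check_number(alpha2_per_C, "alpha2_per_C", lower = 0)
  structure(
    list(l_mm = l_mm, alpha1_per_C = alpha1_per_C,
         alpha2_per_C = alpha2_per_C),
    class = "fp_thermal"
  )
}

#' Expander geometry
#'
#' Geometry of the screw expander carrying the two sensors:
#' anteroposterior separation between the sensors, screw pitch
#' (expansion per full turn) and the turn fraction applied per
#' activation.
#'
#' @param separation_um Distance between the two sensors along the
#'   anteroposterior axis, in micrometres (> 0).
#' @param pitch_mm_per_turn Expansion per full screw turn, in mm (> 0).
#' @param activation_fraction Fraction of a turn applied per activation,
#'   in `(0, 1]`.
#' @return An object of class `fp_geometry`.
#' @examples
#' expander_geometry()
#' @export
expander_geometry <- function(separation_um = 900, pitch_mm_per_turn = 0.8,
                              activation_fraction = 1 / 6) {
  check_number(separation_um, "separation_um", 0, strict_lower = TRUE)
  check_number(pitch_mm_per_turn, "pitch_mm_per_turn", 0, strict_lower = TRUE)
  check_number(activation_fraction, "activation_fraction", 0, 1,
               strict_lower = TRUE)
  structure(
    list(separation_um = separation_um,
         pitch_mm_per_turn = pitch_mm_per_turn,
         activation_fraction = activation_fraction),
    class = "fp_geometry"
  )
}
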