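#' Speed of sound container
#'
#' Holds a speed of sound in the canonical internal unit (mm/us) together
#' with the water temperature it was inferred from (if any) and a 1-sigma
#' uncertainty. Values outside the plausible range for water near ambient
#' conditions (1.3--1.6 mm/us) trigger a warning, not an error, so that
#' deliberately scaled test cases remain expressible.
#'
#' @param value speed of sound.
#' @param unit unit of `value`: `"mm/us"` (default) or `"m/s"`.
#' @param temperature water temperature in degrees Celsius, or `NA`.
#' @param uncertainty 1-sigma uncertainty in the same unit as `value`, or `NA`.
#' @return an object of class `sound_speed` with elements `value` (mm/us),
#'   `temperature` (deg C) and `uncertainty` (mm/us).
#' @examples
#' sound_speed(1482.9, unit = "m/s")
#' @export
sound_speed <- function(value, unit = c("mm/us", "m/s"),
                        temperature = NA_real_, uncertainty = NA_real_) {
  unit <- match.arg(unit)
  stopifnot(length(value) == 1L, is.finite(value), value > 0)
  if (unit == "m/s") {
    value <- m_per_s_to_mm_per_us(value)
    if (is.finite(uncertainty)) uncertainty <- m_per_s_to_mm_per_us(uncertainty)
  }
  if (value < 1.3 || value > 1.6) {
    warning("speed of sound ", signif(value, 5),
            " mm/us is outside the plausible range for water (1.3-1.6)")
  }
  structure(list(value = value, temperature = temperature,
                 uncertainty = uncertainty),
            class = "sound_speed")
}

#' @export
print.sound_speed <- function(x, ...) {
  cat(sprintf("<sound_speed> %.4f mm/us (%.1f m/s)",
              x$value, mm_per_us_to_m_per_s(x$value)))
  if (is.finite(x$temperature)) cat(sprintf(" at %.2f degC", x$temperature))
  if (is.finite(x$uncertainty)) {
    cat(sprintf(" +/- %.4g m/s", mm_per_us_to_m_per_s(x$uncertainty)))
  }
  cat("\n")
  invisible(x)
}

# Marczak (1997) pure-water polynomial, speed in m/s, T in deg C, 0..95 degC.
.marczak_coef <- c(1.402385e3, 5.038813, -5.799136e-2,
                   3.287156e-4, -1.398845e-6, 2.787860e-9)

.marczak_m_per_s <- function(temp_c) {
  drop(outer(temp_c, 0:5, "^") %*% .marczak_coef)
}

.marczak_deriv <- function(temp_c) {
  drop(outer(temp_c, 0:4, "^") %*% (.marczak_coef[-1] * (1:5)))
}

#' Infer the speed of sound in pure water from its temperature
#'
#' Evaluates the fifth-order pure-water polynomial of Marczak (valid
#' 0--95 deg C at ambient pressure). Returns a [sound_speed] whose
#' uncertainty is propagated locally from the temperature resolution:
#' `dc = |dc/dT| * dT`. At 20 deg C and the default 0.1 deg C resolution
#' this is about 0.3 m/s.
#'
#' The relation assumes pure (e.g. deionized) water; salinity and pressure
#' terms are deliberately absent.
#'
#' @param temperature water temperature, deg C, in \[0, 95\].
#' @param temperature_resolution 1-sigma temperature measurement
#'   resolution, deg C (default 0.1).
#' @return a [sound_speed] (value in mm/us).
#' @examples
#' speed_from_temperature(20)  # ~1482.38 m/s
#' @export
speed_from_temperature <- function(temperature, temperature_resolution = 0.1) {
  stopifnot(length(temperature) == 1L, is.finite(temperature))
  if (temperature < 0 || temperature > 95) {
    stop("temperature ", temperature,
         " degC is outside the validity range [0, 95] of the pure-water relation",
         call. = FALSE)
  }
  c_ms <- .marczak_m_per_s(temperature)
  dc_ms <- abs(.marczak_deriv(temperature)) * temperature_resolution
  sound_speed(c_ms, unit = "m/s", temperature = temperature,
              uncertainty = dc_ms)
}

#' Invert the temperature-speed relation
#'
#' Finds the temperature at which pure water has the given speed of sound,
#' by root bisection of the Marczak polynomial on its monotonically
#' increasing branch (0--74 deg C, where the polynomial peaks).
#'
#' @param speed a [sound_speed], or a numeric speed value.
#' @param unit unit of a numeric `speed` (`"mm/us"` or `"m/s"`).
#' @return temperature in deg C.
#' @examples
#' temperature_from_speed(1482.9, unit = "m/s")  # ~20.2 degC
#' @export
temperature_from_speed <- function(speed, unit = c("mm/us", "m/s")) {
  unit <- match.arg(unit)
  c_ms <- if (inherits(speed, "sound_speed")) {
    mm_per_us_to_m_per_s(speed$value)
  } else if (unit == "m/s") speed else mm_per_us_to_m_per_s(speed)
  lo <- .marczak_m_per_s(0); hi <- .marczak_m_per_s(74)
  if (c_ms < lo || c_ms > hi) {
    stop("speed ", signif(c_ms, 6),
         " m/s is outside the invertible range [", round(lo, 1), ", ",
         round(hi, 1), "] m/s (0-74 degC)", call. = FALSE)
  }
  stats::uniroot(function(T) .marczak_m_per_s(T) - c_ms,
                 interval = c(0, 74), tol = 1e-10)$root
}
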