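#' Unit conversion helpers
#'
#' The package works internally in millimetres and microseconds, so that the
#' speed of sound is of order 1 (1482.9 m/s = 1.4829 mm/us), design-matrix
#' entries are of order the source-grid pitch, and right-hand sides are of
#' order the squared distances. Frequencies are in MHz (1/us).
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
m_per_s_to_mm_per_us <- function(x) x / 1000

#' @rdname units
#' @export
mm_per_us_to_m_per_s <- function(x) x * 1000

#' Acoustic wavelength at the array centre frequency
#'
#' @param c_mm_us speed of sound, mm/us (or a [sound_speed] object).
#' @param f_mhz centre frequency, MHz.
#' @return wavelength lambda0 in mm.
#' @export
wavelength_mm <- function(c_mm_us, f_mhz) {
  if (inherits(c_mm_us, "sound_speed")) c_mm_us <- c_mm_us$value
  stopifnot(is.finite(c_mm_us), c_mm_us > 0, is.finite(f_mhz), f_mhz > 0)
  c_mm_us / f_mhz
}

.assert_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop("invalid input: non-finite values in ", what, call. = FALSE)
  }
  invisible(x)
}
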