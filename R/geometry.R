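#' Transducer array geometry
#'
#' An ordered table of transducer elements (designed positions, optional
#' estimated positions, optional per-channel receive delays) together with
#' the array's acoustic properties.
#'
#' @param positions N x 3 numeric matrix of designed element positions, mm.
#' @param center_frequency centre frequency, MHz.
#' @param fractional_bandwidth one-way 6 dB fractional bandwidth,
#'   dimensionless in (0, 2).
#' @param receive_delays optional N-vector of per-channel receive delays, us.
#' @param estimated_positions optional N x 3 matrix of estimated positions, mm.
#' @param index optional integer element indices (default `1:N`), unique.
#' @return an object of class `array_geometry` with elements `positions`,
#'   `estimated_positions`, `receive_delays`, `index`, `center_frequency`,
#'   `fractional_bandwidth`.
#' @seealso [make_array_geometry()] for parametric ring/arc constructions,
#'   [wavelength_mm()] for the wavelength at a stated sound speed.
#' @export
array_geometry <- function(positions, center_frequency,
                           fractional_bandwidth = 0.8,
                           receive_delays = NULL,
                           estimated_positions = NULL,
                           index = NULL) {
  positions <- .as_xyz(positions, "positions")
  n <- nrow(positions)
  stopifnot(n >= 1L)
  stopifnot(length(center_frequency) == 1L, is.finite(center_frequency),
            center_frequency > 0)
  stopifnot(length(fractional_bandwidth) == 1L,
            fractional_bandwidth > 0, fractional_bandwidth < 2)
  if (is.null(receive_delays)) receive_delays <- rep(0, n)
  if (length(receive_delays) != n) {
    stop("invalid input: receive_delays length ", length(receive_delays),
         " does not match the number of elements ", n, call. = FALSE)
  }
  .assert_finite(receive_delays, "receive_delays")
  if (!is.null(estimated_positions)) {
    estimated_positions <- .as_xyz(estimated_positions, "estimated_positions")
    stopifnot(nrow(estimated_positions) == n)
  }
  if (is.null(index)) index <- seq_len(n)
  index <- as.integer(index)
  if (anyDuplicated(index)) {
    stop("invalid input: transducer indices must be unique", call. = FALSE)
  }
  structure(list(positions = positions,
                 estimated_positions = estimated_positions,
                 receive_delays = as.numeric(receive_delays),
                 index = index,
                 center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  r <- sqrt(rowSums(x$positions^2))
  cat(sprintf("<array_geometry> %d elements, f0 = %g MHz, 6 dB bw = %g%%\n",
              nrow(x$positions), x$center_frequency,
              100 * x$fractional_bandwidth))
  cat(sprintf("  radial distance from origin: %.2f-%.2f mm\n",
              min(r), max(r)))
  if (!is.null(x$estimated_positions)) cat("  estimated positions present\n")
  if (any(x$receive_delays != 0)) cat("  nonzero receive delays present\n")
  invisible(x)
}

#' Number of elements of an array geometry
#' @param geometry an [array_geometry].
#' @return integer element count.
#' @export
n_elements <- function(geometry) nrow(geometry$positions)

.as_xyz <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop("invalid input: ", what, " must have 3 columns (x, y, z in mm)",
         call. = FALSE)
  }
  .assert_finite(x, what)
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' Point-source grid in the translation-stage frame
#'
#' Coordinates of the point-source positions visited by the translation
#' stage, expressed in the stage frame (origin at the stage's initial
#' position). For regular grids the pitch and shape are retained.
#'
#' @param positions M x 3 numeric matrix, mm.
#' @param pitch grid pitch in mm (optional, regular grids only).
#' @param shape integer vector `(nx, ny, nz)` (optional, regular grids only).
#' @return an object of class `point_source_grid`.
#' @export
point_source_grid <- function(positions, pitch = NULL, shape = NULL) {
  positions <- .as_xyz(positions, "positions")
  if (nrow(positions) < 2L) {
    stop("insufficient data: a point-source grid needs at least 2 positions",
         call. = FALSE)
  }
  if (anyDuplicated(positions)) {
    warning("duplicated point-source positions; the pairs they form carry no information")
  }
  if (!is.null(shape)) {
    shape <- as.integer(shape)
    stopifnot(length(shape) == 3L, all(shape >= 1L))
    if (prod(shape) != nrow(positions)) {
      stop("invalid input: prod(shape) != number of positions", call. = FALSE)
    }
  }
  structure(list(positions = positions, pitch = pitch, shape = shape),
            class = "point_source_grid")
}

#' Regular rectangular point-source grid
#'
#' Convenience constructor for an `nx x ny x nz` grid with a common pitch,
#' the arrangement used for stage-scanned point-source acquisitions
#' (e.g. 6 x 6 x 3 at 0.254 mm pitch).
#'
#' @param shape integer vector `(nx, ny, nz)`.
#' @param pitch spacing between neighbouring positions, mm.
#' @param origin 3-vector added to all positions, mm (default the grid is
#'   centred on the origin when `center = TRUE`).
#' @param center logical; centre the grid on `origin` (default `TRUE`).
#'   With `center = FALSE` the first grid corner sits at `origin`.
#' @return a [point_source_grid].
#' @examples
#' regular_grid(c(6, 6, 3), pitch = 0.254)
#' @export
regular_grid <- function(shape, pitch, origin = c(0, 0, 0), center = TRUE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), pitch > 0)
  g <- as.matrix(expand.grid(x = seq_len(shape[1]) - 1L,
                             y = seq_len(shape[2]) - 1L,
                             z = seq_len(shape[3]) - 1L)) * pitch
  if (center) g <- sweep(g, 2, colMeans(g))
  g <- sweep(g, 2, as.numeric(origin), "+")
  point_source_grid(g, pitch = pitch, shape = shape)
}

#' @export
print.point_source_grid <- function(x, ...) {
  cat(sprintf("<point_source_grid> M = %d sources", nrow(x$positions)))
  if (!is.null(x$shape)) {
    cat(sprintf(" (%s grid, pitch %g mm)",
                paste(x$shape, collapse = "x"), x$pitch))
  }
  cat("\n")
  invisible(x)
}

#' Time-of-arrival matrix
#'
#' M x N matrix of arrival times (us) for M point sources and N transducers,
#' with a validity mask for channels/sources whose arrival could not be
#' estimated reliably.
#'
#' @param times M x N numeric matrix, us.
#' @param valid M x N logical matrix (default: finite positive entries).
#' @return an object of class `toa_matrix`.
#' @export
toa_matrix <- function(times, valid = NULL) {
  times <- as.matrix(times)
  storage.mode(times) <- "double"
  if (is.null(valid)) valid <- is.finite(times) & times > 0
  valid <- as.matrix(valid)
  stopifnot(identical(dim(valid), dim(times)), is.logical(valid))
  bad <- valid & !(is.finite(times) & times > 0)
  if (any(bad)) {
    stop("invalid input: entries marked valid must be finite and positive",
         call. = FALSE)
  }
  structure(list(times = times, valid = valid), class = "toa_matrix")
}

#' @export
print.toa_matrix <- function(x, ...) {
  cat(sprintf("<toa_matrix> %d sources x %d transducers, %.1f%% valid\n",
              nrow(x$times), ncol(x$times), 100 * mean(x$valid)))
  invisible(x)
}

#' Subtract per-channel receive delays from a ToA matrix
#'
#' Electronic/acoustic receive delays are measured separately (e.g. by
#' diffusing laser light onto the array) and must be removed before the
#' times reflect pure propagation: `t_corrected = t_recorded - delay`.
#'
#' @param toas a [toa_matrix].
#' @param delays N-vector of per-channel delays, us.
#' @return a corrected [toa_matrix]; invalid entries are left untouched.
#' @export
apply_receive_delays <- function(toas, delays) {
  stopifnot(inherits(toas, "toa_matrix"))
  if (length(delays) != ncol(toas$times)) {
    stop("invalid input: delays length ", length(delays),
         " does not match the number of channels ", ncol(toas$times),
         call. = FALSE)
  }
  .assert_finite(delays, "delays")
  times <- sweep(toas$times, 2, as.numeric(delays))
  times[!toas$valid] <- toas$times[!toas$valid]
  toa_matrix(times, toas$valid)
}
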