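#' Band-limited transducer pulse model
#'
#' One-way element response specified, as transducer data sheets do, by a
#' centre frequency and a one-way 6 dB fractional bandwidth of a Gaussian
#' frequency response. The default time-domain kernel is a
#' Gaussian-modulated cosine whose envelope gives exactly the requested
#' bandwidth; `"n_shape_bandpassed"` is the odd (sine-modulated) variant -
#' a band-limited N-shaped wavelet with a leading compression lobe, the
#' shape a photoacoustic point source actually delivers and therefore the
#' kind the back-projection studies use (back-projection of the even
#' kernel focuses a quarter period off). The pulse onset is defined as 3
#' envelope standard deviations before the peak; evaluation support is
#' truncated at 4.
#'
#' @param center_frequency centre frequency, MHz.
#' @param fractional_bandwidth one-way 6 dB fractional bandwidth in (0, 2).
#' @param kind `"gaussian_modulated"` (default) or `"n_shape_bandpassed"`.
#' @return an object of class `pulse_model` with elements `sigma_t`
#'   (envelope standard deviation, us), `sigma_f` (MHz), `onset_us`
#'   (peak-to-onset time, us) and `support_us` (half support, us).
#' @examples
#' pulse_model(2.25, 0.98)
#' @export
pulse_model <- function(center_frequency, fractional_bandwidth = 0.8,
                        kind = c("gaussian_modulated", "n_shape_bandpassed")) {
  kind <- match.arg(kind)
  stopifnot(center_frequency > 0,
            fractional_bandwidth > 0, fractional_bandwidth < 2)
  # |A(f)| = exp(-(f - f0)^2 / (2 sigma_f^2)) falls to 1/2 at
  # f0 +/- bw * f0 / 2  =>  sigma_f = bw * f0 / (2 sqrt(2 log 2))
  sigma_f <- fractional_bandwidth * center_frequency / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth,
                 kind = kind,
                 sigma_f = sigma_f, sigma_t = sigma_t,
                 onset_us = 3 * sigma_t, support_us = 4 * sigma_t),
            class = "pulse_model")
}

#' @export
print.pulse_model <- function(x, ...) {
  cat(sprintf("<pulse_model> %s, f0 = %g MHz, 6 dB bw = %g%%, sigma_t = %.4g us\n",
              x$kind, x$center_frequency, 100 * x$fractional_bandwidth,
              x$sigma_t))
  invisible(x)
}

#' Evaluate a pulse kernel
#'
#' @param pulse a [pulse_model].
#' @param tau times relative to the pulse peak, us (vector or matrix).
#' @return kernel values, same shape as `tau`; zero outside the truncated
#'   support.
#' @export
pulse_eval <- function(pulse, tau) {
  stopifnot(inherits(pulse, "pulse_model"))
  env <- exp(-tau^2 / (2 * pulse$sigma_t^2))
  env[abs(tau) > pulse$support_us] <- 0
  ph <- 2 * pi * pulse$center_frequency * tau
  # the N-shaped kernel leads with the compression (positive) lobe and
  # falls through zero at tau = 0, as a photoacoustic wavelet does
  if (pulse$kind == "gaussian_modulated") env * cos(ph) else -env * sin(ph)
}

#' Parametric transducer array constructions
#'
#' Builds the element layouts used by ring- and hemisphere-style PACT
#' systems:
#' \describe{
#'   \item{`ring`}{`n_elements` uniformly spaced on a circle of the given
#'     radius in the z = 0 plane (angular pitch `2 pi / n`).}
#'   \item{`arc`}{`n_elements` uniformly spaced on a meridian arc spanning
#'     `angular_span` degrees of elevation measured from the equator at
#'     azimuth `azimuth`; the default 180 degrees is a full meridian
#'     (equator - pole - opposite equator), the shape of the arc arrays
#'     mounted in hemispherical housings.}
#'   \item{`hemisphere_arcs`}{`n_arcs` such arcs uniformly distributed in
#'     azimuth.}
#' }
#' `rotations` lists additional azimuthal rotations (degrees) of the whole
#' arrangement; each rotation duplicates the elements as virtual positions
#' (the acquisition trick used to densify angular coverage).
#'
#' @param type `"ring"`, `"arc"` or `"hemisphere_arcs"`.
#' @param radius array radius, mm.
#' @param n_elements physical elements per ring/arc.
#' @param angular_span arc span in degrees of elevation (default 180, a
#'   full meridian).
#' @param azimuth azimuth of the (first) arc, degrees (default 0).
#' @param n_arcs number of arcs for `"hemisphere_arcs"` (default 4).
#' @param rotations numeric vector of extra azimuthal rotations, degrees
#'   (default none).
#' @param center_frequency,fractional_bandwidth acoustic properties passed
#'   to [array_geometry()].
#' @return an [array_geometry] (virtual elements included).
#' @examples
#' make_array_geometry("ring", radius = 100, n_elements = 512,
#'                     center_frequency = 2, fractional_bandwidth = 0.8)
#' @export
make_array_geometry <- function(type = c("ring", "arc", "hemisphere_arcs"),
                                radius, n_elements,
                                angular_span = 180, azimuth = 0, n_arcs = 4,
                                rotations = numeric(),
                                center_frequency = 2.25,
                                fractional_bandwidth = 0.98) {
  type <- match.arg(type)
  stopifnot(radius > 0, n_elements >= 1)
  deg <- pi / 180
  if (type == "ring") {
    ang <- 2 * pi * (seq_len(n_elements) - 1) / n_elements
    pos <- radius * cbind(cos(ang), sin(ang), 0)
  } else {
    if (angular_span <= 0) {
      stop("invalid input: arc angular span must be positive", call. = FALSE)
    }
    elev <- deg * angular_span * (seq_len(n_elements) - 0.5) / n_elements
    azis <- if (type == "arc") azimuth else azimuth + 360 * (0:(n_arcs - 1)) / n_arcs
    pos <- do.call(rbind, lapply(azis, function(a) {
      radius * cbind(cos(elev) * cos(deg * a),
                     cos(elev) * sin(deg * a),
                     sin(elev))
    }))
  }
  if (length(rotations)) {
    rot <- function(p, a) {
      ca <- cos(deg * a); sa <- sin(deg * a)
      cbind(ca * p[, 1] - sa * p[, 2], sa * p[, 1] + ca * p[, 2], p[, 3])
    }
    pos <- do.call(rbind, c(list(pos), lapply(rotations, rot, p = pos)))
  }
  array_geometry(pos, center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth)
}

#' Randomly perturb transducer positions
#'
#' Adds an independent uniform offset in `[-max_shift, +max_shift]` to each
#' selected coordinate of every element, emulating manufacturing errors
#' (e.g. a maximum shift of half a wavelength).
#'
#' @param geometry an [array_geometry].
#' @param max_shift maximum absolute offset, mm (>= 0).
#' @param axes subset of `c("x", "y", "z")` to perturb (default x and y).
#' @param seed integer seed; the perturbation is reproducible.
#' @return a new [array_geometry] with perturbed `positions` (acoustic
#'   properties and delays carried over).
#' @export
perturb_positions <- function(geometry, max_shift, axes = c("x", "y"),
                              seed = 1L) {
  stopifnot(inherits(geometry, "array_geometry"), max_shift >= 0)
  axes <- match.arg(axes, c("x", "y", "z"), several.ok = TRUE)
  pos <- geometry$positions
  if (max_shift > 0) {
    set.seed(as.integer(seed))
    cols <- match(axes, c("x", "y", "z"))
    for (j in cols) {
      pos[, j] <- pos[, j] + stats::runif(nrow(pos), -max_shift, max_shift)
    }
  }
  array_geometry(pos, center_frequency = geometry$center_frequency,
                 fractional_bandwidth = geometry$fractional_bandwidth,
                 receive_delays = geometry$receive_delays,
                 index = geometry$index)
}

# shared time-axis construction with coverage check; the default origin
# leaves 12% of the record signal-free so the default noise window of the
# ToA estimator precedes every arrival
.sim_time_axis <- function(t_min, t_max, pulse, sampling_rate, duration,
                           time_origin, worst_pair = NULL) {
  if (is.null(duration)) {  # shortest record covering all arrivals + padding
    duration <- (t_max - t_min + 2 * pulse$support_us + 2 / sampling_rate) / 0.88
  }
  if (is.null(time_origin)) {
    time_origin <- max(0, t_min - pulse$support_us - 0.12 * duration)
  }
  t_end <- time_origin + duration
  if (t_max + pulse$support_us > t_end) {
    extra <- if (is.null(worst_pair)) "" else
      sprintf(" (latest arrival: source %d, transducer %d)",
              worst_pair[1], worst_pair[2])
    stop(sprintf(paste0("truncation: duration %.4g us ending at %.4g us does not ",
                        "cover the latest arrival %.4g us plus pulse support%s"),
                 duration, t_end, t_max, extra), call. = FALSE)
  }
  tg <- seq(time_origin, t_end, by = 1 / sampling_rate)
  list(time_origin = time_origin, tgrid = tg)
}

#' Simulate point-source calibration waveforms
#'
#' Forward model for the calibration acquisition: each record is the pulse
#' kernel centred on the predicted arrival time `||x - x'|| / c`, scaled by
#' `1/distance` for spherical spreading, optionally shifted by the
#' per-channel receive delay and a random ToA jitter, with additive white
#' Gaussian noise. Transducers are treated as isotropic points.
#'
#' @param geometry an [array_geometry]; its `positions` are taken as the
#'   true element positions.
#' @param grid a [point_source_grid], or a plain K x 3 matrix of source
#'   positions (a single row simulates one isolated point source).
#' @param c a [sound_speed] or numeric mm/us.
#' @param pulse a [pulse_model].
#' @param sampling_rate MHz.
#' @param duration record length, us; `NULL` (default) fits the record to
#'   the arrival-time span plus padding.
#' @param time_origin time of the first sample, us; default places it just
#'   before the earliest arrival.
#' @param noise_std additive noise standard deviation, relative to the
#'   maximum clean amplitude of the set (default 0).
#' @param delays optional N-vector of receive delays, us (default the
#'   geometry's).
#' @param toa_jitter standard deviation of per-record arrival jitter, us.
#' @param seed integer seed for noise and jitter.
#' @return a [waveform_set] (M x N x T) carrying the delays used.
#' @export
simulate_point_waveforms <- function(geometry, grid, c, pulse,
                                     sampling_rate = 40, duration = NULL,
                                     time_origin = NULL, noise_std = 0,
                                     delays = NULL, toa_jitter = 0,
                                     seed = 1L) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(pulse, "pulse_model"))
  src <- if (inherits(grid, "point_source_grid")) grid$positions else
    .as_xyz(grid, "grid")
  cv <- .speed_value(c)
  if (is.null(delays)) delays <- geometry$receive_delays
  d <- .pairwise_dist(src, geometry$positions)  # M x N
  t_arr <- sweep(d / cv, 2, delays, "+")
  m <- nrow(t_arr); n <- ncol(t_arr)
  set.seed(as.integer(seed))
  if (toa_jitter > 0) {
    t_arr <- t_arr + matrix(stats::rnorm(m * n, 0, toa_jitter), m, n)
  }
  wp <- arrayInd(which.max(t_arr), dim(t_arr))
  ax <- .sim_time_axis(min(t_arr), max(t_arr), pulse, sampling_rate,
                       duration, time_origin, worst_pair = wp)
  tt <- length(ax$tgrid)
  samples <- array(0, dim = c(m, n, tt))
  for (jn in seq_len(n)) {
    tau <- outer(-t_arr[, jn], ax$tgrid, "+")  # M x T, t - t_arr
    samples[, jn, ] <- (1 / d[, jn]) * pulse_eval(pulse, tau)
  }
  if (noise_std > 0) {
    s <- noise_std * max(abs(samples))
    samples <- samples + array(stats::rnorm(length(samples), 0, s), dim(samples))
  }
  waveform_set(samples, sampling_rate = sampling_rate,
               time_origin = ax$time_origin, receive_delays = delays)
}

#' Generate a vessel-like numerical phantom
#'
#' Curvilinear branching structures built from smoothed random walks and
#' rasterized with a per-branch width, used as the initial-pressure target
#' of the simulation demonstrations. The phantom is synthetic: it stands in
#' for vasculature only in the sense of being a sparse set of bright,
#' smooth, elongated structures.
#'
#' @param shape integer 2- or 3-vector of voxel counts (>= 32 per axis for
#'   a meaningful demo; a third entry of 1 gives a planar phantom).
#' @param spacing voxel pitch, mm.
#' @param n_branches number of branches (0 gives an empty phantom).
#' @param width_range 2-vector of branch widths (diameters), mm.
#' @param seed integer seed; construction is deterministic.
#' @return a `phantom` (also a `volume`): voxel values in \[0, 1\], with
#'   attribute `centerlines` (list of K x 3 matrices, mm).
#' @export
make_vessel_phantom <- function(shape, spacing = 0.25, n_branches = 4,
                                width_range = c(0.6, 1.4), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  stopifnot(length(shape) == 3L, all(shape >= 1L), spacing > 0,
            n_branches >= 0, length(width_range) == 2L,
            all(width_range > 0))
  ext <- shape * spacing
  origin <- -(shape - 1) * spacing / 2  # centre the phantom on the origin
  vals <- array(0, dim = shape)
  planar <- shape[3] == 1L
  set.seed(as.integer(seed))
  centerlines <- list()
  widths <- numeric(0)
  step <- spacing / 2
  for (b in seq_len(n_branches)) {
    w <- stats::runif(1, width_range[1], width_range[2])
    # start inside the central 60% of the extent
    p <- (stats::runif(3) - 0.5) * 0.6 * ext
    if (planar) p[3] <- 0
    th <- stats::runif(1, 0, 2 * pi)
    ph <- if (planar) 0 else stats::runif(1, -0.3, 0.3)
    dir <- c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
    nstep <- ceiling(0.6 * max(ext) / step)
    pts <- matrix(NA_real_, nstep, 3)
    for (k in seq_len(nstep)) {
      pts[k, ] <- p
      th <- th + stats::rnorm(1, 0, 0.1)
      if (!planar) ph <- 0.95 * ph + stats::rnorm(1, 0, 0.03)
      dir <- c(cos(ph) * cos(th), cos(ph) * sin(th), sin(ph))
      p <- p + step * dir
      if (any(abs(p) > 0.48 * ext[seq_along(p)])) break
    }
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (!nrow(pts)) next
    centerlines[[length(centerlines) + 1L]] <- pts
    widths <- c(widths, w)
    vals <- .stamp_tube(vals, origin, spacing, pts, w / 2)
  }
  ph <- structure(list(values = vals, origin = origin,
                       spacing = rep(spacing, 3)),
                  class = c("phantom", "volume"))
  attr(ph, "centerlines") <- centerlines
  attr(ph, "widths") <- widths
  ph
}

# mark voxels within `radius` of any of the centreline points
.stamp_tube <- function(vals, origin, spacing, pts, radius) {
  shape <- dim(vals)
  rad_vox <- ceiling(radius / spacing)
  for (k in seq_len(nrow(pts))) {
    ctr <- (pts[k, ] - origin) / spacing + 1  # fractional voxel index
    lo <- pmax(floor(ctr - rad_vox), 1)
    hi <- pmin(ceiling(ctr + rad_vox), shape)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- origin[1] + (ix - 1) * spacing
    gy <- origin[2] + (iy - 1) * spacing
    gz <- origin[3] + (iz - 1) * spacing
    dd <- outer(outer((gx - pts[k, 1])^2, (gy - pts[k, 2])^2, "+"),
                (gz - pts[k, 3])^2, "+")
    sel <- which(dd <= radius^2, arr.ind = TRUE)
    if (nrow(sel)) {
      vals[cbind(ix[sel[, 1]], iy[sel[, 2]], iz[sel[, 3]])] <- 1
    }
  }
  vals
}

#' Simulate waveforms radiated by a phantom
#'
#' Discrete-source superposition: every nonzero voxel of the phantom emits
#' the pulse kernel delayed by its propagation time and weighted by its
#' value over the distance (spherical spreading). A single-voxel phantom is
#' therefore identical to [simulate_point_waveforms()] for that location,
#' and the operator is linear in the phantom.
#'
#' @param geometry an [array_geometry] (true element positions).
#' @param phantom a `phantom`/`volume` of initial pressure.
#' @param c a [sound_speed] or numeric mm/us.
#' @param pulse a [pulse_model].
#' @param sampling_rate MHz.
#' @param duration record length, us; `NULL` (default) fits the record to
#'   the arrival-time span plus padding.
#' @param time_origin time of the first sample, us (default: just before
#'   the earliest arrival).
#' @return a [waveform_set] with a single source dimension (1 x N x T).
#' @export
simulate_phantom_waveforms <- function(geometry, phantom, c, pulse,
                                       sampling_rate = 40, duration = NULL,
                                       time_origin = NULL) {
  stopifnot(inherits(geometry, "array_geometry"), inherits(phantom, "volume"),
            inherits(pulse, "pulse_model"))
  cv <- .speed_value(c)
  nz <- which(phantom$values > 0)
  n <- n_elements(geometry)
  if (!length(nz)) {
    ax <- .sim_time_axis(0, 0, pulse, sampling_rate, duration, time_origin)
    return(waveform_set(array(0, c(1, n, length(ax$tgrid))),
                        sampling_rate, ax$time_origin,
                        receive_delays = geometry$receive_delays))
  }
  src <- voxel_coordinates(phantom)[nz, , drop = FALSE]
  w <- phantom$values[nz]
  d <- .pairwise_dist(src, geometry$positions)  # K x N
  t_arr <- d / cv
  wp <- arrayInd(which.max(t_arr), dim(t_arr))
  ax <- .sim_time_axis(min(t_arr), max(t_arr), pulse, sampling_rate,
                       duration, time_origin,
                       worst_pair = c(wp[1], wp[2]))
  tt <- length(ax$tgrid)
  samples <- array(0, dim = c(1, n, tt))
  for (jn in seq_len(n)) {
    tau <- outer(-t_arr[, jn], ax$tgrid, "+")  # K x T
    samples[1, jn, ] <- colSums((w / d[, jn]) * pulse_eval(pulse, tau))
  }
  waveform_set(samples, sampling_rate = sampling_rate,
               time_origin = ax$time_origin,
               receive_delays = geometry$receive_delays)
}
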