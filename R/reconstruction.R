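#' Voxel volume container
#'
#' A 3D array of reconstructed (or phantom) values with the world
#' coordinates of its voxel centres: voxel `(i, j, k)` is centred at
#' `origin + ((i, j, k) - 1) * spacing`, all in mm.
#'
#' @param values 3D numeric array.
#' @param origin 3-vector, centre of voxel (1, 1, 1), mm.
#' @param spacing voxel pitch, mm; scalar or per-axis 3-vector.
#' @return an object of class `volume`.
#' @export
volume <- function(values, origin = c(0, 0, 0), spacing = 1) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  .assert_finite(values, "values")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing (%s) mm, origin (%s) mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' World coordinates of all voxel centres
#' @param vol a `volume`.
#' @return (nx * ny * nz) x 3 matrix, mm, in array (column-major) order.
#' @export
voxel_coordinates <- function(vol) {
  d <- dim(vol$values)
  ax <- lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a])
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

#' Universal back-projection reconstruction
#'
#' Filter-and-sum reconstruction of the initial pressure: each channel is
#' filtered to `2 p(t) - 2 t dp/dt` (time derivative by central
#' differences, one-sided at the record boundaries) and back-projected
#' over spherical shells: every voxel accumulates the filtered value
#' sampled, by linear interpolation, at its propagation time
#' `t = ||voxel - element|| / c` (plus the per-channel receive delay when
#' the records are uncorrected), weighted by the element's solid angle.
#' With uniformly spaced elements the default weights are uniform; a
#' cosine-weighted mode down-weights oblique incidence.
#'
#' @param waveforms a [waveform_set] with a single source record
#'   (1 x N x T), or an N x T matrix (then `sampling_rate` and
#'   `time_origin` must be given).
#' @param positions N x 3 matrix of element positions, mm.
#' @param c a [sound_speed] or numeric mm/us.
#' @param origin,shape,spacing reconstruction region: centre of the first
#'   voxel (mm), voxel counts, and voxel pitch (mm, scalar or 3-vector).
#' @param weights `"uniform"` (default) or `"cosine"` (incidence-angle
#'   weighting towards the region centre).
#' @param element_weights optional N-vector of per-element solid-angle
#'   weights (relative `dOmega`), for layouts whose elements do not tile
#'   the detection surface uniformly - e.g. meridian arcs sample a sphere
#'   with areal density `1 / cos(elevation)`, so their elements represent
#'   solid angles proportional to `cos(elevation)`. Combined
#'   multiplicatively with `weights`.
#' @param sampling_rate,time_origin metadata when `waveforms` is a matrix.
#' @param receive_delays optional N-vector, us, overriding the waveform
#'   set's delays.
#' @return a `volume`. Voxels whose arrival time falls outside the record
#'   contribute nothing; if any do, a coverage warning reports the
#'   fraction.
#' @export
ubp_reconstruct <- function(waveforms, positions, c, origin, shape,
                            spacing, weights = c("uniform", "cosine"),
                            element_weights = NULL,
                            sampling_rate = NULL, time_origin = NULL,
                            receive_delays = NULL) {
  weights <- match.arg(weights)
  cv <- .speed_value(c)
  if (inherits(waveforms, "waveform_set")) {
    if (dim(waveforms$samples)[1] != 1L) {
      stop("invalid input: reconstruction expects a single-record waveform set",
           call. = FALSE)
    }
    p <- matrix(waveforms$samples[1, , ], nrow = dim(waveforms$samples)[2])
    sampling_rate <- waveforms$sampling_rate
    time_origin <- waveforms$time_origin
    if (is.null(receive_delays)) receive_delays <- waveforms$receive_delays
  } else {
    p <- as.matrix(waveforms)
    if (is.null(sampling_rate) || is.null(time_origin)) {
      stop("invalid input: matrix input needs sampling_rate and time_origin",
           call. = FALSE)
    }
  }
  positions <- .as_xyz(positions, "positions")
  n <- nrow(positions)
  if (nrow(p) != n) {
    stop("invalid input: ", nrow(p), " channels but ", n, " positions",
         call. = FALSE)
  }
  if (is.null(receive_delays)) receive_delays <- rep(0, n)
  if (is.null(element_weights)) element_weights <- rep(1, n)
  stopifnot(length(element_weights) == n, all(element_weights >= 0))
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  tt <- ncol(p)
  dt <- 1 / sampling_rate
  tax <- time_origin + (seq_len(tt) - 1) * dt

  # filtered term 2 p - 2 t dp/dt per channel
  dp <- p
  dp[, 2:(tt - 1)] <- (p[, 3:tt] - p[, 1:(tt - 2)]) / (2 * dt)
  dp[, 1] <- (p[, 2] - p[, 1]) / dt
  dp[, tt] <- (p[, tt] - p[, tt - 1]) / dt
  filt <- 2 * p - 2 * sweep(dp, 2, tax, "*")

  vol <- volume(array(0, dim = shape), origin = origin, spacing = spacing)
  vox <- voxel_coordinates(vol)
  nv <- nrow(vox)
  acc <- numeric(nv)
  wsum <- 0
  misses <- 0
  ctr <- origin + (shape - 1) * spacing / 2
  for (jn in seq_len(n)) {
    dx <- vox[, 1] - positions[jn, 1]
    dy <- vox[, 2] - positions[jn, 2]
    dz <- vox[, 3] - positions[jn, 3]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    s <- (r / cv + receive_delays[jn] - time_origin) / dt + 1
    k <- floor(s)
    inb <- k >= 1 & k < tt
    misses <- misses + sum(!inb)
    kk <- k[inb]
    frac <- s[inb] - kk
    val <- numeric(nv)
    row <- filt[jn, ]
    val[inb] <- row[kk] * (1 - frac) + row[kk + 1] * frac
    val <- val * element_weights[jn]
    w <- element_weights[jn]
    if (weights == "cosine") {
      # cosine of the angle between element->voxel and element->region centre
      ed <- ctr - positions[jn, ]
      edn <- sqrt(sum(ed^2))
      cosw <- pmax((dx * ed[1] + dy * ed[2] + dz * ed[3]) / (r * edn), 0)
      val <- val * cosw
      w <- w * mean(cosw)
    }
    acc <- acc + val
    wsum <- wsum + w
  }
  if (misses > 0) {
    warning(sprintf("coverage: %.2f%% of voxel-channel samples fell outside the records",
                    100 * misses / (as.numeric(nv) * n)))
  }
  vol$values <- array(acc / wsum, dim = shape)
  vol
}
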