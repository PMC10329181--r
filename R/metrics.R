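#' Covariance-based size and spread of a reconstructed target
#'
#' Treats the squared volume as an (unnormalized) 3D probability density
#' over the voxel centres - the 3D generalization of the power-RMS width
#' of a signal - and summarizes its covariance matrix `Sigma` by
#' `size = sqrt(det(Sigma))` (mm^3, a volume measure) and
#' `spread = sqrt(tr(Sigma))` (mm, a radial extent measure). Both are
#' invariant under rotation, translation and intensity scaling of the
#' volume; negative values are squared, not clipped, and no background is
#' subtracted. The density support is the analyzed region, so the metrics
#' depend (weakly, for a compact target) on the region extent.
#'
#' @param vol a `volume` with nonzero energy.
#' @return list with `size` (mm^3), `spread` (mm), `covariance`
#'   (3 x 3, mm^2) and `centroid` (mm).
#' @export
compute_size_spread <- function(vol) {
  stopifnot(inherits(vol, "volume"))
  w <- as.numeric(vol$values)^2
  s <- sum(w)
  if (s <= 0) {
    stop("undefined metric: volume has zero energy", call. = FALSE)
  }
  w <- w / s
  vox <- voxel_coordinates(vol)
  mu <- colSums(vox * w)
  d <- sweep(vox, 2, mu)
  sigma <- crossprod(d, d * w)
  dimnames(sigma) <- list(c("x", "y", "z"), c("x", "y", "z"))
  list(size = sqrt(max(det(sigma), 0)),
       spread = sqrt(sum(diag(sigma))),
       covariance = sigma,
       centroid = mu)
}

#' Contrast-to-noise ratio between two voxel regions
#'
#' `CNR = (mean(signal ROI) - mean(background ROI)) / sd(background ROI)`.
#'
#' @param vol a `volume`.
#' @param signal_roi logical mask (same shape as the volume) or voxel
#'   indices of the signal region.
#' @param background_roi mask or indices of the background region;
#'   disjoint from the signal region.
#' @return CNR (dimensionless).
#' @seealso [default_rois()] for a reproducible mask construction.
#' @export
compute_cnr <- function(vol, signal_roi, background_roi) {
  stopifnot(inherits(vol, "volume"))
  v <- vol$values
  si <- if (is.logical(signal_roi)) which(signal_roi) else as.integer(signal_roi)
  bi <- if (is.logical(background_roi)) which(background_roi) else as.integer(background_roi)
  if (!length(si) || !length(bi)) {
    stop("invalid input: empty ROI", call. = FALSE)
  }
  if (length(intersect(si, bi))) {
    stop("invalid input: signal and background ROIs overlap", call. = FALSE)
  }
  sdb <- stats::sd(v[bi])
  if (!is.finite(sdb) || sdb == 0) {
    stop("undefined metric: background ROI has zero variance", call. = FALSE)
  }
  (mean(v[si]) - mean(v[bi])) / sdb
}

#' Default signal/background ROI masks for a compact bright target
#'
#' Signal: voxels at or above `signal_threshold` times the maximum.
#' Background: voxels outside the signal bounding box scaled by
#' `background_factor` about its centre.
#'
#' @param vol a `volume`.
#' @param signal_threshold fraction of the maximum (default 0.5).
#' @param background_factor bounding-box scale factor (default 3).
#' @return list of logical arrays `signal` and `background`.
#' @export
default_rois <- function(vol, signal_threshold = 0.5, background_factor = 3) {
  stopifnot(inherits(vol, "volume"))
  v <- vol$values
  sig <- v >= signal_threshold * max(v)
  idx <- which(sig, arr.ind = TRUE)
  ctr <- colMeans(idx)
  half <- pmax((apply(idx, 2, max) - apply(idx, 2, min)) / 2, 0.5)
  d <- dim(v)
  ax <- lapply(1:3, function(a) {
    abs(seq_len(d[a]) - ctr[a]) > background_factor * half[a]
  })
  outside <- outer(outer(ax[[1]], ax[[2]], "|"), ax[[3]], "|")
  list(signal = sig, background = outside & !sig)
}

#' Full width at half maximum of a sampled profile
#'
#' Width between the half-maximum crossings adjacent to the (unique
#' global) peak, with linear interpolation between samples.
#'
#' @param profile numeric vector of sampled values.
#' @param spacing sample spacing, mm.
#' @return FWHM in mm.
#' @export
compute_fwhm <- function(profile, spacing = 1) {
  stopifnot(is.numeric(profile), length(profile) >= 3L, spacing > 0)
  k <- which.max(profile)
  half <- profile[k] / 2
  below_l <- which(profile[seq_len(k)] < half)
  below_r <- which(profile[k:length(profile)] < half)
  if (!length(below_l) || !length(below_r)) {
    stop("undefined metric: profile does not cross half maximum on both sides",
         call. = FALSE)
  }
  il <- max(below_l)            # last sample below half, left of peak
  ir <- k - 1 + min(below_r)    # first sample below half, right of peak
  xl <- il + (half - profile[il]) / (profile[il + 1] - profile[il])
  xr <- (ir - 1) + (half - profile[ir - 1]) / (profile[ir] - profile[ir - 1])
  (xr - xl) * spacing
}

#' Root-mean-square position error between two coordinate sets
#'
#' @param true_positions N x 3 matrix, mm.
#' @param estimated_positions N x 3 matrix, mm.
#' @return list with `per_axis` (named 3-vector of per-axis RMSE, mm) and
#'   `total` (RMSE of the Euclidean errors, mm).
#' @export
position_rmse <- function(true_positions, estimated_positions) {
  a <- .as_xyz(true_positions, "true_positions")
  b <- .as_xyz(estimated_positions, "estimated_positions")
  if (nrow(a) != nrow(b)) {
    stop("invalid input: coordinate sets have different lengths", call. = FALSE)
  }
  e <- b - a
  per_axis <- sqrt(colMeans(e^2))
  names(per_axis) <- c("x", "y", "z")
  list(per_axis = per_axis, total = sqrt(mean(rowSums(e^2))))
}
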