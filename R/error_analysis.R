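#' Error budget for calibration error propagation
#'
#' Stated 1-sigma magnitudes of the two measurement errors that dominate
#' the calibration, plus the error model that says how they are shared
#' across a transducer's measurements:
#' \describe{
#'   \item{`systematic_per_transducer`}{one speed-of-sound error and one ToA
#'     offset common to all of a transducer's records (a threshold-induced
#'     first-arrival offset has this structure). The paired right-hand
#'     sides then only feel the differential term `c dt (d_i - d_j)`, but
#'     the least-squares solve maps that difference pattern back to a
#'     near-radial displacement of about `c dt` (plus `2 D dc / c` from the
#'     speed error at distance D), so the resulting error is almost
#'     independent of the grid.}
#'   \item{`independent_per_measurement`}{an independent ToA error per
#'     source record (speed error still shared). Per-axis errors then
#'     scale like `c dt D / (sqrt(M) s_axis)` with `s_axis` the grid
#'     coordinate spread, which is the regime in which adding sources or
#'     pitch helps.}
#' }
#'
#' @param sound_speed_error 1-sigma speed-of-sound error, m/s (default 0.3,
#'   the local slope of the temperature relation times a 0.1 deg C
#'   resolution).
#' @param toa_error 1-sigma ToA error, us (default 0.45, about one period
#'   of a 2.25 MHz centre frequency).
#' @param toa_error_model `"systematic_per_transducer"` (default) or
#'   `"independent_per_measurement"`.
#' @param tolerance target per-axis position error, mm (e.g. lambda0 / 5);
#'   optional, used by [design_grid()].
#' @return an object of class `error_budget`.
#' @export
error_budget <- function(sound_speed_error = 0.3, toa_error = 0.45,
                         toa_error_model = c("systematic_per_transducer",
                                             "independent_per_measurement"),
                         tolerance = NULL) {
  toa_error_model <- match.arg(toa_error_model)
  stopifnot(sound_speed_error >= 0, toa_error >= 0)
  if (!is.null(tolerance)) stopifnot(tolerance > 0)
  structure(list(sound_speed_error = sound_speed_error,
                 toa_error = toa_error,
                 toa_error_model = toa_error_model,
                 tolerance = tolerance),
            class = "error_budget")
}

#' @export
print.error_budget <- function(x, ...) {
  cat(sprintf("<error_budget> dc = %g m/s, dt = %g us (%s)\n",
              x$sound_speed_error, x$toa_error, x$toa_error_model))
  if (!is.null(x$tolerance)) cat(sprintf("  tolerance %g mm per axis\n", x$tolerance))
  invisible(x)
}

# Shared pieces of the first-order propagation: the pseudo-inverse of the
# pair design matrix and the sensitivity of b to dc and dt.
.propagation_pieces <- function(grid, position, c, pairs = "all") {
  cv <- .speed_value(c)
  t_true <- drop(.pairwise_dist(grid$positions, matrix(position, nrow = 1))) / cv
  sys <- assemble_system(grid, t_true, cv, pairs = pairs)
  sv <- svd(sys$A)
  if (sum(sv$d > 1e-8 * sv$d[1]) < 3L) {
    stop("degenerate geometry: source grid does not span three dimensions",
         call. = FALSE)
  }
  P <- sv$v %*% (t(sv$u) / sv$d)  # (A'A)^-1 A', 3 x Nc
  d <- cv * t_true
  i <- sys$pair_index[, 1]; j <- sys$pair_index[, 2]
  list(P = P, d = d, i = i, j = j, cv = cv, t = t_true, sys = sys)
}

#' Predict the covariance of one estimated transducer position
#'
#' First-order propagation of the error budget through the pairwise
#' least-squares estimator. A measured distance perturbs as
#' `d_i -> d_i + t_i dc + c dt_i`, so each right-hand side perturbs by
#' `db = (dc / c)(d_i^2 - d_j^2) + c (d_i dt_i - d_j dt_j)`, and the
#' position error is `pinv(A) db`. The covariance honours the correlation
#' structure of the chosen error model (see [error_budget()]).
#'
#' @param grid a [point_source_grid].
#' @param position nominal 3-vector transducer position, mm.
#' @param c a [sound_speed] or numeric mm/us.
#' @param budget an [error_budget].
#' @param pairs `"all"` or `"anchored"` pair enumeration.
#' @return 3 x 3 covariance matrix, mm^2, with attribute `sd` (per-axis
#'   standard deviations, mm).
#' @export
predict_position_covariance <- function(grid, position, c, budget,
                                        pairs = "all") {
  stopifnot(inherits(budget, "error_budget"))
  pp <- .propagation_pieces(grid, position, c, pairs)
  sc <- m_per_s_to_mm_per_us(budget$sound_speed_error)  # mm/us
  st <- budget$toa_error
  g_c <- (pp$d[pp$i]^2 - pp$d[pp$j]^2) / pp$cv
  xc <- pp$P %*% g_c
  cov <- sc^2 * tcrossprod(xc)
  if (budget$toa_error_model == "systematic_per_transducer") {
    g_t <- pp$cv * (pp$d[pp$i] - pp$d[pp$j])
    xt <- pp$P %*% g_t
    cov <- cov + st^2 * tcrossprod(xt)
  } else {
    m <- nrow(grid$positions)
    B <- matrix(0, nrow(pp$sys$A), m)
    B[cbind(seq_along(pp$i), pp$i)] <- pp$d[pp$i]
    B[cbind(seq_along(pp$j), pp$j)] <- B[cbind(seq_along(pp$j), pp$j)] - pp$d[pp$j]
    PB <- pp$P %*% B
    cov <- cov + (pp$cv * st)^2 * tcrossprod(PB)
  }
  dimnames(cov) <- list(c("x", "y", "z"), c("x", "y", "z"))
  attr(cov, "sd") <- sqrt(diag(cov))
  cov
}

#' Monte-Carlo check of the predicted position error
#'
#' Simulates noisy ToA sets according to the budget's error model, solves
#' each trial with the same pairwise estimator, and reports the empirical
#' per-axis standard deviation and bias of the estimates. Serves as the
#' independent verification of [predict_position_covariance()].
#'
#' @inheritParams predict_position_covariance
#' @param trials number of Monte-Carlo trials (>= 100).
#' @param seed integer seed for reproducibility.
#' @return list with `sd` (per-axis standard deviation, mm), `bias`
#'   (per-axis mean error, mm), `trials`.
#' @export
monte_carlo_position_error <- function(grid, position, c, budget,
                                       trials = 10000L, seed = 1L,
                                       pairs = "all") {
  stopifnot(inherits(budget, "error_budget"), trials >= 100L)
  pp <- .propagation_pieces(grid, position, c, pairs)
  m <- nrow(grid$positions)
  r2 <- rowSums(grid$positions^2)
  sc <- m_per_s_to_mm_per_us(budget$sound_speed_error)
  st <- budget$toa_error
  systematic <- budget$toa_error_model == "systematic_per_transducer"
  set.seed(as.integer(seed))
  est <- matrix(0, trials, 3)
  chunk <- 500L
  done <- 0L
  while (done < trials) {
    nb <- min(chunk, trials - done)
    dc <- rnorm(nb, 0, sc)
    dt <- if (systematic) {
      matrix(rnorm(nb, 0, st), nrow = m, ncol = nb, byrow = TRUE)
    } else {
      matrix(rnorm(m * nb, 0, st), nrow = m)
    }
    # measured distances: assumed speed (c + dc) times measured times (t + dt)
    dhat <- sweep(pp$t + dt, 2, pp$cv + dc, "*")
    h <- dhat^2 / 2
    b <- h[pp$i, , drop = FALSE] - h[pp$j, , drop = FALSE] +
      (r2[pp$j] - r2[pp$i]) / 2
    est[done + seq_len(nb), ] <- t(pp$P %*% b)
    done <- done + nb
  }
  err <- sweep(est, 2, position)
  list(sd = apply(err, 2, stats::sd),
       bias = colMeans(err),
       trials = trials)
}

#' Size a point-source grid to an error tolerance
#'
#' Evaluates the predicted per-axis position error for every candidate
#' grid (all shape x pitch combinations) at each nominal transducer
#' position and returns the smallest candidate (fewest sources, pitch as
#' tie-break) whose worst-case per-axis error meets the tolerance.
#'
#' @param tolerance per-axis error tolerance, mm (overrides
#'   `budget$tolerance` when given).
#' @param candidate_pitches numeric vector of pitches, mm.
#' @param candidate_shapes list of integer 3-vectors `(nx, ny, nz)`.
#' @param c a [sound_speed] or numeric mm/us.
#' @param budget an [error_budget].
#' @param nominal_positions K x 3 matrix of representative transducer
#'   positions, mm.
#' @return list with `grid` (the chosen [point_source_grid]), `pitch`,
#'   `shape`, `worst_sd` (worst-case per-axis sd, mm), `margin`
#'   (`tolerance - max(worst_sd)`), and `table` (all candidates). Raises an
#'   error reporting the best achievable candidate if none satisfies the
#'   tolerance.
#' @export
design_grid <- function(tolerance = NULL, candidate_pitches, candidate_shapes,
                        c, budget, nominal_positions) {
  stopifnot(inherits(budget, "error_budget"))
  if (is.null(tolerance)) tolerance <- budget$tolerance
  if (is.null(tolerance)) {
    stop("invalid input: no tolerance given (neither argument nor budget)",
         call. = FALSE)
  }
  stopifnot(length(candidate_pitches) >= 1L, length(candidate_shapes) >= 1L)
  nominal_positions <- .as_xyz(nominal_positions, "nominal_positions")
  cand <- expand.grid(pitch = candidate_pitches,
                      shape = seq_along(candidate_shapes))
  rows <- lapply(seq_len(nrow(cand)), function(k) {
    shape <- as.integer(candidate_shapes[[cand$shape[k]]])
    pitch <- cand$pitch[k]
    g <- regular_grid(shape, pitch)
    sds <- apply(nominal_positions, 1, function(p) {
      attr(predict_position_covariance(g, p, c, budget), "sd")
    })
    worst <- apply(matrix(sds, nrow = 3), 1, max)
    data.frame(nx = shape[1], ny = shape[2], nz = shape[3],
               m = prod(shape), pitch = pitch,
               sd_x = worst[1], sd_y = worst[2], sd_z = worst[3],
               sd_max = max(worst))
  })
  tab <- do.call(rbind, rows)
  tab$meets <- tab$sd_max <= tolerance
  ord <- order(tab$m, tab$pitch)
  tab <- tab[ord, ]
  hit <- which(tab$meets)
  if (!length(hit)) {
    best <- tab[which.min(tab$sd_max), ]
    stop(sprintf(paste0("no candidate grid meets the tolerance %.4g mm; best ",
                        "achievable is %.4g mm with a %dx%dx%d grid at %.3g mm ",
                        "pitch - increase the pitch or the number of sources"),
                 tolerance, best$sd_max, best$nx, best$ny, best$nz, best$pitch),
         call. = FALSE)
  }
  pick <- tab[hit[1], ]
  shape <- c(pick$nx, pick$ny, pick$nz)
  list(grid = regular_grid(shape, pick$pitch),
       pitch = pick$pitch, shape = shape,
       worst_sd = c(x = pick$sd_x, y = pick$sd_y, z = pick$sd_z),
       margin = tolerance - pick$sd_max,
       table = tab)
}
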