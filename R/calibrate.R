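#' Forward time-of-arrival model
#'
#' Time of arrival of a spherical wavefront emitted at `source_position`
#' and received at `transducer_position`:
#' `t = ||x - x'|| / c`.
#'
#' @param transducer_position 3-vector, mm.
#' @param source_position 3-vector, mm.
#' @param c a [sound_speed] or a numeric speed in mm/us.
#' @return arrival time in us (non-negative scalar).
#' @examples
#' predict_toa(c(10, 0, 0), c(0, 0, 0), sound_speed(1.4829))
#' @export
predict_toa <- function(transducer_position, source_position, c) {
  cv <- .speed_value(c)
  stopifnot(length(transducer_position) == 3L, length(source_position) == 3L)
  .assert_finite(transducer_position, "transducer_position")
  .assert_finite(source_position, "source_position")
  sqrt(sum((transducer_position - source_position)^2)) / cv
}

#' Predict the full ToA matrix for an array and a source grid
#'
#' Vectorized forward model over all source/transducer pairs, optionally
#' adding per-channel receive delays (so the synthetic values mimic
#' recorded, uncorrected arrival times).
#'
#' @param geometry an [array_geometry]; its `estimated_positions` are used
#'   when present and `use = "estimated"`, otherwise the designed positions.
#' @param grid a [point_source_grid].
#' @param c a [sound_speed] or numeric mm/us.
#' @param use `"designed"` (default) or `"estimated"` positions.
#' @param add_receive_delays logical; add the geometry's receive delays.
#' @return a [toa_matrix] (M sources x N transducers).
#' @export
predict_toa_matrix <- function(geometry, grid, c, use = c("designed", "estimated"),
                               add_receive_delays = FALSE) {
  use <- match.arg(use)
  cv <- .speed_value(c)
  pos <- if (use == "estimated") {
    if (is.null(geometry$estimated_positions)) {
      stop("invalid input: geometry has no estimated positions", call. = FALSE)
    }
    geometry$estimated_positions
  } else geometry$positions
  d <- .pairwise_dist(grid$positions, pos)
  t <- d / cv
  if (add_receive_delays) t <- sweep(t, 2, geometry$receive_delays, "+")
  toa_matrix(t)
}

# M x N distances between rows of a (M x 3) and rows of b (N x 3)
.pairwise_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.speed_value <- function(c) {
  v <- if (inherits(c, "sound_speed")) c$value else c
  stopifnot(length(v) == 1L, is.finite(v), v > 0)
  v
}

#' Assemble the pairwise linear system for one transducer
#'
#' Squaring the ToA relation for two sources and differencing eliminates
#' the quadratic term in the unknown transducer position `x`, leaving for
#' every source pair (i, j) one linear equation
#' `(x'_j - x'_i) . x = (d_i^2 - d_j^2 + r'_j^2 - r'_i^2) / 2`
#' with `d = c t` and `r'^2 = ||x'||^2`. With `r'_i = 0` this is the law of
#' cosines for the triangle formed by the origin, source j and the
#' transducer. Pairs involving an invalid ToA and pairs of coincident
#' sources (zero rows) are dropped.
#'
#' @param grid a [point_source_grid].
#' @param toas M-vector of arrival times, us.
#' @param c a [sound_speed] or numeric mm/us.
#' @param valid optional M-vector logical mask (default: finite positive).
#' @param pairs `"all"` for all `choose(M, 2)` pairs (default), or
#'   `"anchored"` for the M - 1 pairs sharing one reference source.
#' @param anchor index of the reference source for `pairs = "anchored"`.
#' @return an object of class `pair_equation_set`: list with `A` (Nc x 3
#'   design matrix, mm), `b` (Nc-vector, mm^2) and `pair_index` (Nc x 2).
#' @export
assemble_system <- function(grid, toas, c, valid = NULL,
                            pairs = c("all", "anchored"), anchor = 1L) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(grid, "point_source_grid"))
  cv <- .speed_value(c)
  pos <- grid$positions
  m <- nrow(pos)
  stopifnot(length(toas) == m)
  if (is.null(valid)) valid <- is.finite(toas) & toas > 0
  keep <- which(valid)
  if (length(keep) < 2L) {
    stop("insufficient data: fewer than 2 valid point-source measurements",
         call. = FALSE)
  }
  if (pairs == "anchored") {
    anchor <- as.integer(anchor)
    if (!(anchor %in% keep)) {
      stop("invalid input: anchor source ", anchor, " is not valid", call. = FALSE)
    }
    others <- setdiff(keep, anchor)
    pr <- cbind(rep(anchor, length(others)), others)
  } else {
    pr <- t(utils::combn(keep, 2L))
  }
  d2 <- (cv * toas)^2
  r2 <- rowSums(pos^2)
  A <- pos[pr[, 2], , drop = FALSE] - pos[pr[, 1], , drop = FALSE]
  b <- (d2[pr[, 1]] - d2[pr[, 2]] + r2[pr[, 2]] - r2[pr[, 1]]) / 2
  nz <- rowSums(A^2) > 0  # coincident sources carry no information
  structure(list(A = A[nz, , drop = FALSE], b = b[nz],
                 pair_index = pr[nz, , drop = FALSE]),
            class = "pair_equation_set")
}

#' @export
print.pair_equation_set <- function(x, ...) {
  cat(sprintf("<pair_equation_set> Nc = %d equations in 3 unknowns\n",
              nrow(x$A)))
  invisible(x)
}

#' Solve a pairwise system for one transducer position
#'
#' Minimum-norm least-squares solution `x = pinv(A) b` via the singular
#' value decomposition. Rank is decided by a singular-value threshold
#' relative to the largest singular value; a numerical rank below 3 (all
#' sources coplanar or collinear) or a condition number above
#' `condition_limit` raises a degenerate-geometry error naming the
#' direction that cannot be resolved.
#'
#' @param system a `pair_equation_set` from [assemble_system()].
#' @param condition_limit reject systems with condition number above this
#'   (default 1e6); a warning is emitted above `condition_warn` (1e4).
#' @param condition_warn warning tier for the condition number.
#' @param rank_tol relative singular-value threshold (default 1e-8).
#' @return list with `position` (3-vector, mm), `residual_norm`
#'   (`||A x - b||`, mm^2), `condition_number`, `singular_values`.
#' @export
solve_position <- function(system, condition_limit = 1e6,
                           condition_warn = 1e4, rank_tol = 1e-8) {
  stopifnot(inherits(system, "pair_equation_set"))
  A <- system$A; b <- system$b
  if (nrow(A) < 3L) {
    stop("insufficient data: fewer than 3 pair equations", call. = FALSE)
  }
  sv <- svd(A)
  s <- sv$d
  rank <- sum(s > rank_tol * s[1])
  if (rank < 3L) {
    dir <- sv$v[, which(s <= rank_tol * s[1])[1]]
    ax <- c("x", "y", "z")[which.max(abs(dir))]
    stop(sprintf(paste0("degenerate geometry: source arrangement has rank %d; ",
                        "direction (%.3f, %.3f, %.3f) (mostly %s) is unresolved ",
                        "- sources are coplanar or collinear"),
                 rank, dir[1], dir[2], dir[3], ax), call. = FALSE)
  }
  cond <- s[1] / s[3]
  if (cond > condition_limit) {
    stop(sprintf(paste0("degenerate geometry: condition number %.3g exceeds ",
                        "limit %.3g; weakest direction (%.3f, %.3f, %.3f)"),
                 cond, condition_limit, sv$v[1, 3], sv$v[2, 3], sv$v[3, 3]),
         call. = FALSE)
  }
  if (cond > condition_warn) {
    warning(sprintf("ill-conditioned source arrangement (condition number %.3g)",
                    cond))
  }
  x <- sv$v %*% ((crossprod(sv$u, b)) / s)
  list(position = drop(x),
       residual_norm = sqrt(sum((A %*% x - b)^2)),
       condition_number = cond,
       singular_values = s)
}

#' Calibrate every transducer of an array
#'
#' Runs the pairwise linearization and pseudo-inverse solve independently
#' for each transducer. Transducers whose system is degenerate, masked out,
#' or otherwise unsolvable are flagged (`calibrated = FALSE`) and retain
#' their designed coordinates in the output so that downstream
#' reconstruction always has a complete coordinate set.
#'
#' @param grid a [point_source_grid] (stage-frame source positions).
#' @param toas a [toa_matrix] (M sources x N transducers). Arrival times
#'   must already be corrected for receive delays unless `receive_delays`
#'   is supplied here.
#' @param c a [sound_speed] or numeric mm/us.
#' @param geometry an [array_geometry] providing designed positions for
#'   reporting shifts and for fallback coordinates.
#' @param receive_delays optional N-vector of delays, us, subtracted before
#'   solving.
#' @param pairs,condition_limit passed to [assemble_system()] /
#'   [solve_position()].
#' @return an object of class `calibration_result`: list with
#'   `positions` (N x 3 estimated, mm; designed for failed channels),
#'   `calibrated` (logical N), `residual_norm`, `condition_number`,
#'   `shift_mm` (distance designed -> estimated), `messages` (per-channel
#'   failure messages), `geometry`.
#' @export
calibrate_array <- function(grid, toas, c, geometry,
                            receive_delays = NULL,
                            pairs = c("all", "anchored"),
                            condition_limit = 1e6) {
  pairs <- match.arg(pairs)
  stopifnot(inherits(toas, "toa_matrix"), inherits(geometry, "array_geometry"))
  n <- n_elements(geometry)
  if (ncol(toas$times) != n) {
    stop("invalid input: ToA matrix has ", ncol(toas$times),
         " channels but the geometry has ", n, call. = FALSE)
  }
  if (!is.null(receive_delays)) toas <- apply_receive_delays(toas, receive_delays)
  est <- geometry$positions
  ok <- logical(n)
  res <- cond <- rep(NA_real_, n)
  msgs <- character(n)
  for (j in seq_len(n)) {
    fit <- tryCatch({
      sys <- assemble_system(grid, toas$times[, j], c,
                             valid = toas$valid[, j], pairs = pairs)
      solve_position(sys, condition_limit = condition_limit)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      msgs[j] <- conditionMessage(fit)
    } else {
      est[j, ] <- fit$position
      res[j] <- fit$residual_norm
      cond[j] <- fit$condition_number
      ok[j] <- TRUE
    }
  }
  if (!any(ok)) {
    stop("calibration failed for every transducer; first failure: ", msgs[1],
         call. = FALSE)
  }
  shift <- sqrt(rowSums((est - geometry$positions)^2))
  structure(list(positions = est, calibrated = ok,
                 residual_norm = res, condition_number = cond,
                 shift_mm = shift, messages = msgs, geometry = geometry),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d/%d transducers calibrated\n",
              sum(x$calibrated), length(x$calibrated)))
  s <- x$shift_mm[x$calibrated]
  if (length(s)) {
    cat(sprintf("  shift vs designed: median %.4g mm, max %.4g mm\n",
                stats::median(s), max(s)))
  }
  if (any(!x$calibrated)) {
    cat("  uncalibrated channels retain designed coordinates:",
        paste(utils::head(which(!x$calibrated), 10L), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate a calibration result
#'
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return data.frame with one row per transducer: index, designed and
#'   estimated coordinates, shift, residual, condition number, flag.
#' @export
as.data.frame.calibration_result <- function(x, ...) {
  g <- x$geometry
  data.frame(index = g$index,
             x_design = g$positions[, 1], y_design = g$positions[, 2],
             z_design = g$positions[, 3],
             x_mm = x$positions[, 1], y_mm = x$positions[, 2],
             z_mm = x$positions[, 3],
             shift_mm = x$shift_mm,
             residual_norm = x$residual_norm,
             condition_number = x$condition_number,
             calibrated = x$calibrated)
}
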