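test_that("forward ToA model is distance over speed", {
  cs <- fix_speed()
  x <- c(3, -2, 7)
  expect_equal(predict_toa(x, x, cs), 0)
  expect_equal(predict_toa(c(14.829, 0, 0), c(0, 0, 0), sound_speed(1.4829)),
               10)
  t1 <- predict_toa(c(5, 0, 0), c(0, 0, 0), cs)
  t2 <- predict_toa(c(10, 0, 0), c(0, 0, 0), cs)
  expect_equal(t2, 2 * t1)
  expect_error(predict_toa(c(NA, 0, 0), c(0, 0, 0), cs), "invalid input")
})

test_that("pairwise rows and right-hand sides follow the squared-difference form", {
  grid <- point_source_grid(rbind(c(0, 0, 0), c(1, 0, 0)))
  # distances 10 and 9 mm at c = 1 mm/us
  sys <- assemble_system(grid, c(10, 9), 1)
  expect_equal(drop(sys$A), c(x = 1, y = 0, z = 0))
  expect_equal(sys$b, (100 - 81 + 1 - 0) / 2)
  expect_equal(sys$b, 10)  # consistent with a transducer at x = 10 mm

  # with r'_1 = 0 the rhs is the law-of-cosines combination
  s2 <- c(2, 1, 2)
  grid2 <- point_source_grid(rbind(c(0, 0, 0), s2))
  d <- c(10, 8.5)
  sys2 <- assemble_system(grid2, d, 1)
  expect_equal(unname(sys2$b), (d[1]^2 - d[2]^2 + sum(s2^2)) / 2)
})

test_that("invalid ToAs and coincident sources drop out of the system", {
  cs <- fix_speed()
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  grid <- suppressWarnings(point_source_grid(pos))
  t <- fix_toas_one(c(5, 4, 3), grid, cs)
  sys <- assemble_system(grid, t, cs)
  # the duplicated pair contributes a zero row, which is excluded
  expect_true(all(rowSums(sys$A^2) > 0))
  expect_equal(nrow(sys$A), choose(4, 2) - 1)

  sysv <- assemble_system(grid, t, cs, valid = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(nrow(sysv$A), choose(3, 2))
  expect_error(assemble_system(grid, t, cs, valid = c(TRUE, FALSE, FALSE, FALSE)),
               "insufficient data")
})

test_that("noiseless solve recovers the transducer exactly", {
  cs <- fix_speed()
  grid <- point_source_grid(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                  c(0, 0, 1)))
  x0 <- c(7, -3, 2)
  t <- fix_toas_one(x0, grid, cs)
  fit <- solve_position(assemble_system(grid, t, cs))
  expect_lt(max(abs(fit$position - x0)), 1e-9)
  expect_lt(fit$residual_norm, 1e-9)
})

test_that("coplanar sources raise a degenerate-geometry error naming the axis", {
  cs <- fix_speed()
  grid <- point_source_grid(cbind(expand.grid(x = 0:2, y = 0:2), z = 0))
  t <- fix_toas_one(c(5, 5, 40), grid, cs)
  expect_error(solve_position(assemble_system(grid, t, cs)),
               "degenerate geometry.*z")
})

test_that("a tight condition-number limit rejects near-degenerate grids", {
  cs <- fix_speed()
  pos <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = c(0, 1e-4)))
  grid <- point_source_grid(pos)
  t <- fix_toas_one(c(5, 5, 40), grid, cs)
  sys <- assemble_system(grid, t, cs)
  expect_error(solve_position(sys, condition_limit = 1e3),
               "condition number")
  expect_warning(try(solve_position(sys), silent = TRUE),
                 "ill-conditioned")
})

test_that("solution is unbiased under zero-mean rhs perturbations", {
  cs <- fix_speed()
  grid <- fix_grid()
  x0 <- c(12, -8, 20)
  sys <- assemble_system(grid, fix_toas_one(x0, grid, cs), cs)
  set.seed(42)
  est <- matrix(0, 2000, 3)
  for (k in seq_len(nrow(est))) {
    noisy <- sys
    noisy$b <- sys$b + rnorm(length(sys$b), 0, 0.5)
    est[k, ] <- solve_position(noisy)$position
  }
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - x0) < 4 * se + 1e-9))
})

test_that("anchored pairs give the same noiseless solution as all pairs", {
  cs <- fix_speed()
  grid <- fix_grid()
  x0 <- c(25, 10, -15)
  t <- fix_toas_one(x0, grid, cs)
  fa <- solve_position(assemble_system(grid, t, cs, pairs = "all"))
  fn <- solve_position(assemble_system(grid, t, cs, pairs = "anchored"))
  expect_lt(max(abs(fa$position - fn$position)), 1e-9)
})

test_that("pseudo-inverse agrees with normal equations and a direct minimizer", {
  cs <- fix_speed()
  grid <- fix_grid()
  x0 <- c(18, -5, 9)
  sys <- assemble_system(grid, fix_toas_one(x0, grid, cs), cs)
  set.seed(7)
  sys$b <- sys$b + rnorm(length(sys$b), 0, 0.3)
  xs <- solve_position(sys)$position
  xn <- drop(solve(crossprod(sys$A), crossprod(sys$A, sys$b)))
  obj <- function(x) sum((sys$A %*% x - sys$b)^2)
  grd <- function(x) drop(2 * crossprod(sys$A, sys$A %*% x - sys$b))
  xo <- optim(x0, obj, grd, method = "BFGS",
              control = list(reltol = 1e-15, maxit = 500))$par
  expect_lt(max(abs(xs - xn)), 1e-8)
  expect_lt(max(abs(xs - xo)), 1e-8)
})

test_that("whole-array calibration recovers a perturbed ring from noiseless ToAs", {
  cs <- fix_speed()
  geom <- fix_ring(n = 64)
  pert <- perturb_positions(geom, 0.375, seed = 5)
  grid <- regular_grid(c(4, 4, 3), pitch = 2)
  toas <- predict_toa_matrix(pert, grid, cs)
  cal <- calibrate_array(grid, toas, cs, geom)
  expect_true(all(cal$calibrated))
  expect_lt(max(abs(cal$positions - pert$positions)), 1e-6)
  expect_equal(cal$shift_mm,
               sqrt(rowSums((pert$positions - geom$positions)^2)),
               tolerance = 1e-6)
})

test_that("estimates are equivariant under stage-frame translation", {
  cs <- fix_speed()
  geom <- fix_ring(n = 8)
  grid <- fix_grid()
  toas <- predict_toa_matrix(geom, grid, cs)
  v <- c(3.3, -1.7, 2.9)
  grid_t <- point_source_grid(sweep(grid$positions, 2, v, "+"))
  cal <- calibrate_array(grid, toas, cs, geom)
  cal_t <- calibrate_array(grid_t, toas, cs, geom)
  expect_equal(cal_t$positions, sweep(cal$positions, 2, v, "+"),
               tolerance = 1e-9)
})

test_that("joint scaling of coordinates and speed leaves ToAs valid and scales estimates", {
  cs <- fix_speed()
  geom <- fix_ring(n = 8)
  grid <- fix_grid()
  toas <- predict_toa_matrix(geom, grid, cs)  # ToAs unchanged below
  a <- 2.7
  grid_s <- point_source_grid(grid$positions * a)
  geom_s <- array_geometry(geom$positions * a, geom$center_frequency,
                           geom$fractional_bandwidth)
  cal <- calibrate_array(grid, toas, cs, geom)
  cal_s <- suppressWarnings(
    calibrate_array(grid_s, toas, cs$value * a, geom_s))
  expect_equal(cal_s$positions, a * cal$positions, tolerance = 1e-9)
})

test_that("degenerate channels are flagged and keep designed coordinates", {
  cs <- fix_speed()
  geom <- fix_ring(n = 6)
  grid <- fix_grid()
  toas <- predict_toa_matrix(geom, grid, cs)
  valid <- toas$valid
  valid[3:nrow(valid), 2] <- FALSE  # channel 2 keeps only 2 sources
  toas2 <- toa_matrix(toas$times, valid)
  cal <- calibrate_array(grid, toas2, cs, geom)
  expect_false(cal$calibrated[2])
  expect_true(all(cal$calibrated[-2]))
  expect_equal(cal$positions[2, ], geom$positions[2, ])
  expect_match(cal$messages[2], "insufficient data")
  df <- as.data.frame(cal)
  expect_equal(nrow(df), 6)
  expect_false(df$calibrated[2])
})

test_that("calibration aborts only when every transducer fails", {
  cs <- fix_speed()
  geom <- fix_ring(n = 4)
  grid <- point_source_grid(cbind(expand.grid(x = 0:2, y = 0:2), z = 0))
  toas <- predict_toa_matrix(geom, grid, cs)
  expect_error(calibrate_array(grid, toas, cs, geom), "every transducer")
})
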