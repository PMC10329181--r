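cs_exp <- sound_speed(1482.9, unit = "m/s")
x_nom <- 120 * c(0.5, 0.5, sqrt(0.5))  # mid-arc element at 120 mm

test_that("a zero error budget predicts zero covariance and zero spread", {
  grid <- regular_grid(c(4, 4, 3), 0.254)
  b0 <- error_budget(sound_speed_error = 0, toa_error = 0)
  cov <- predict_position_covariance(grid, x_nom, cs_exp, b0)
  expect_equal(max(abs(cov)), 0)
  mc <- monte_carlo_position_error(grid, x_nom, cs_exp, b0,
                                   trials = 200, seed = 1)
  expect_equal(max(mc$sd), 0, tolerance = 1e-12)
  expect_equal(max(abs(mc$bias)), 0, tolerance = 1e-9)
})

test_that("analytic propagation matches Monte Carlo for both error models", {
  grid <- regular_grid(c(4, 4, 3), 0.254)
  for (mdl in c("systematic_per_transducer", "independent_per_measurement")) {
    b <- error_budget(toa_error_model = mdl)
    an <- attr(predict_position_covariance(grid, x_nom, cs_exp, b), "sd")
    mc <- monte_carlo_position_error(grid, x_nom, cs_exp, b,
                                     trials = 2000, seed = 2)
    expect_equal(mc$sd, unname(an), tolerance = 0.1)
  }
})

test_that("anchored-pair propagation is also confirmed by Monte Carlo", {
  grid <- regular_grid(c(4, 4, 3), 0.254)
  b <- error_budget()
  an <- attr(predict_position_covariance(grid, x_nom, cs_exp, b,
                                         pairs = "anchored"), "sd")
  mc <- monte_carlo_position_error(grid, x_nom, cs_exp, b,
                                   trials = 2000, seed = 3, pairs = "anchored")
  expect_equal(mc$sd, unname(an), tolerance = 0.1)
})

test_that("Monte-Carlo bias vanishes as trials grow for symmetric noise", {
  grid <- regular_grid(c(3, 3, 2), 0.3)
  b <- error_budget(toa_error_model = "independent_per_measurement")
  m1 <- monte_carlo_position_error(grid, x_nom, cs_exp, b,
                                   trials = 500, seed = 4)
  m2 <- monte_carlo_position_error(grid, x_nom, cs_exp, b,
                                   trials = 20000, seed = 4)
  expect_lt(sqrt(sum(m2$bias^2)), sqrt(sum(m1$bias^2)))
})

test_that("adding sources shrinks the per-measurement covariance", {
  b <- error_budget(toa_error_model = "independent_per_measurement")
  g_small <- regular_grid(c(4, 4, 2), 0.3)
  g_large <- point_source_grid(rbind(g_small$positions,
                                     regular_grid(c(3, 3, 3), 0.25,
                                                  origin = c(0, 0, 0.9))$positions))
  c_small <- diag(predict_position_covariance(g_small, x_nom, cs_exp, b))
  c_large <- diag(predict_position_covariance(g_large, x_nom, cs_exp, b))
  expect_true(all(c_large < c_small))
})

test_that("per-axis error tracks the inverse grid extent per axis", {
  b <- error_budget(toa_error_model = "independent_per_measurement")
  wide <- regular_grid(c(5, 5, 5), 0.3)
  flat <- regular_grid(c(5, 5, 5), 0.3)
  flat$positions[, 3] <- flat$positions[, 3] / 3  # shrink only z extent
  sd_w <- attr(predict_position_covariance(wide, x_nom, cs_exp, b), "sd")
  sd_f <- attr(predict_position_covariance(flat, x_nom, cs_exp, b), "sd")
  expect_gt(sd_f["z"], 2 * sd_w["z"])
  expect_equal(sd_f["x"], sd_w["x"], tolerance = 0.15)
  # and a larger pitch reduces every axis at fixed source count
  fine <- regular_grid(c(4, 4, 3), 0.254)
  coarse <- regular_grid(c(4, 4, 3), 0.508)
  expect_true(all(attr(predict_position_covariance(coarse, x_nom, cs_exp, b), "sd") <
                    attr(predict_position_covariance(fine, x_nom, cs_exp, b), "sd")))
})

test_that("degenerate (planar) grids are rejected", {
  flat <- point_source_grid(cbind(expand.grid(x = 0:3, y = 0:3), z = 0))
  b <- error_budget()
  expect_error(predict_position_covariance(flat, x_nom, cs_exp, b),
               "degenerate geometry")
  expect_error(monte_carlo_position_error(flat, x_nom, cs_exp, b,
                                          trials = 100, seed = 1),
               "degenerate geometry")
})

test_that("design_grid returns the smallest candidate meeting the tolerance", {
  # a budget the estimator can actually satisfy: small independent ToA noise
  b <- error_budget(sound_speed_error = 0.02, toa_error = 0.002,
                    toa_error_model = "independent_per_measurement")
  shapes <- list(c(3, 3, 3), c(4, 4, 3), c(6, 6, 3))
  noms <- rbind(x_nom, 120 * c(sqrt(0.5), 0, sqrt(0.5)))
  rec <- design_grid(tolerance = Inf, candidate_pitches = c(0.254, 0.5),
                     candidate_shapes = shapes, c = cs_exp, budget = b,
                     nominal_positions = noms)
  expect_equal(rec$shape, c(3, 3, 3))
  expect_equal(rec$pitch, 0.254)

  # predicted error decreases monotonically with the source count
  tab <- rec$table
  at_pitch <- tab[tab$pitch == 0.5, ]
  expect_true(all(diff(at_pitch$sd_max[order(at_pitch$m)]) < 0))

  lam5 <- wavelength_mm(cs_exp, 2.25) / 5
  rec2 <- design_grid(tolerance = lam5, candidate_pitches = c(0.254, 0.5),
                      candidate_shapes = shapes, c = cs_exp, budget = b,
                      nominal_positions = noms)
  expect_true(all(rec2$worst_sd <= lam5))
  expect_gte(rec2$margin, 0)
  expect_error(design_grid(tolerance = 1e-9,
                           candidate_pitches = 0.254,
                           candidate_shapes = shapes, c = cs_exp, budget = b,
                           nominal_positions = noms),
               "best achievable")
})
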