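test_that("ring geometry places elements uniformly at the stated radius", {
  g <- make_array_geometry("ring", radius = 100, n_elements = 512,
                           center_frequency = 2, fractional_bandwidth = 0.8)
  r <- sqrt(rowSums(g$positions^2))
  expect_equal(r, rep(100, 512), tolerance = 1e-12)
  ang <- atan2(g$positions[, 2], g$positions[, 1])
  dang <- diff(ang[1:256])
  expect_equal(dang, rep(2 * pi / 512, 255), tolerance = 1e-9)
  expect_true(all(g$positions[, 3] == 0))
})

test_that("arc and hemisphere constructions stay on the sphere", {
  expect_error(make_array_geometry("arc", radius = 100, n_elements = 16,
                                   angular_span = 0), "span")
  h <- make_array_geometry("hemisphere_arcs", radius = 80, n_elements = 256,
                           n_arcs = 4, rotations = 45)
  expect_equal(n_elements(h), 2048)
  expect_equal(sqrt(rowSums(h$positions^2)), rep(80, 2048), tolerance = 1e-9)
  a <- make_array_geometry("arc", radius = 120, n_elements = 256,
                           rotations = 90)
  expect_equal(n_elements(a), 512)
  # the rotated copy is the same arc about the z axis
  expect_equal(a$positions[257:512, 3], a$positions[1:256, 3])
})

test_that("position perturbation respects bounds, axes and seeds", {
  g <- fix_ring(n = 64)
  expect_equal(perturb_positions(g, 0)$positions, g$positions)
  lam0 <- wavelength_mm(1.5, 2)  # 0.75 mm
  p1 <- perturb_positions(g, 0.5 * lam0, seed = 9)
  off <- p1$positions - g$positions
  expect_true(all(abs(off[, 1:2]) <= 0.375))
  expect_true(all(off[, 3] == 0))
  expect_equal(perturb_positions(g, 0.5 * lam0, seed = 9)$positions,
               p1$positions)
  expect_false(all(perturb_positions(g, 0.5 * lam0, seed = 10)$positions ==
                     p1$positions))

  big <- make_array_geometry("ring", radius = 500, n_elements = 5000,
                             center_frequency = 2, fractional_bandwidth = 0.8)
  offb <- perturb_positions(big, 0.375, seed = 1)$positions - big$positions
  expect_lt(abs(mean(offb[, 1:2])), 0.01)
  expect_gt(max(offb[, 1:2]), 0.95 * 0.375)
  expect_lt(min(offb[, 1:2]), -0.95 * 0.375)
})

test_that("simulated arrivals, amplitudes and determinism follow the forward model", {
  cs <- fix_speed()
  geom <- fix_ring(n = 4, radius = 40)
  pulse <- pulse_model(2, 0.8)
  fs <- 40
  src <- rbind(c(0, 0, 0), c(8, 0, 0))
  wf <- simulate_point_waveforms(geom, src, cs, pulse, sampling_rate = fs)
  tax <- waveform_times(wf)
  d <- sqrt(rowSums((matrix(geom$positions[1, ], 2, 3, byrow = TRUE) - src)^2))
  for (m in 1:2) {
    first <- min(which(abs(wf$samples[m, 1, ]) > 0))
    onset_pred <- d[m] / cs$value - pulse$support_us
    expect_lt(abs(tax[first] - onset_pred), 1.5 / fs)
    pk <- max(wf$samples[m, 1, ])
    expect_equal(pk, 1 / d[m], tolerance = 0.03)  # spherical spreading
  }
  # doubling the distance halves the peak (two transducers on one line)
  pair <- array_geometry(rbind(c(10, 0, 0), c(20, 0, 0)),
                         center_frequency = 2, fractional_bandwidth = 0.8)
  wf2 <- simulate_point_waveforms(pair, rbind(c(0, 0, 0), c(0, 5, 0)), cs,
                                  pulse, sampling_rate = fs)
  expect_equal(max(wf2$samples[1, 1, ]) / max(wf2$samples[1, 2, ]), 2,
               tolerance = 0.03)

  wn1 <- simulate_point_waveforms(geom, src, cs, pulse, sampling_rate = fs,
                                  noise_std = 0.05, seed = 13)
  wn2 <- simulate_point_waveforms(geom, src, cs, pulse, sampling_rate = fs,
                                  noise_std = 0.05, seed = 13)
  expect_identical(wn1$samples, wn2$samples)

  expect_error(simulate_point_waveforms(geom, src, cs, pulse,
                                        sampling_rate = fs, duration = 5),
               "truncation.*source")
})

test_that("simulated spectra hit the requested one-way 6 dB bandwidth", {
  for (kind in c("gaussian_modulated", "n_shape_bandpassed")) {
    pulse <- pulse_model(2.25, 0.98, kind = kind)
    fs <- 100
    tau <- seq(-8, 8, by = 1 / fs)
    s <- pulse_eval(pulse, tau)
    n <- length(s)
    spec <- abs(fft(s))[1:(n %/% 2)]
    freq <- (seq_len(n %/% 2) - 1) * fs / n
    mag <- function(f) approx(freq, spec, f)$y
    f0 <- freq[which.max(spec)]
    expect_equal(f0, 2.25, tolerance = 0.02)
    half <- 0.98 * 2.25 / 2
    expect_equal(mag(2.25 + half) / mag(2.25), 0.5, tolerance = 0.05)
    expect_equal(mag(2.25 - half) / mag(2.25), 0.5, tolerance = 0.05)
  }
})

test_that("vessel phantoms are deterministic, bounded and centreline-hugging", {
  expect_equal(sum(make_vessel_phantom(c(40, 40), n_branches = 0)$values), 0)
  ph <- make_vessel_phantom(c(48, 48, 1), spacing = 0.3, n_branches = 4,
                            width_range = c(0.5, 1), seed = 31)
  expect_gt(sum(ph$values > 0), 0)
  cl <- attr(ph, "centerlines")
  wd <- attr(ph, "widths")
  expect_equal(length(cl), length(wd))
  nz <- which(ph$values > 0)
  vox <- voxel_coordinates(ph)[nz, , drop = FALSE]
  dmin <- rep(Inf, nrow(vox))
  for (b in seq_along(cl)) {
    dd <- apply(cl[[b]], 1, function(p) {
      sqrt((vox[, 1] - p[1])^2 + (vox[, 2] - p[2])^2 + (vox[, 3] - p[3])^2)
    })
    dmin <- pmin(dmin, apply(dd, 1, min) - wd[b] / 2)
  }
  expect_true(all(dmin <= 1e-9))

  ph2 <- make_vessel_phantom(c(48, 48, 1), spacing = 0.3, n_branches = 4,
                             width_range = c(0.5, 1), seed = 31)
  expect_identical(ph$values, ph2$values)
  ph3 <- make_vessel_phantom(c(48, 48, 1), spacing = 0.3, n_branches = 4,
                             width_range = c(0.5, 1), seed = 32)
  expect_false(identical(ph$values, ph3$values))
})

test_that("phantom waveforms are a superposition of point responses", {
  cs <- fix_speed()
  geom <- fix_ring(n = 8, radius = 40)
  pulse <- pulse_model(2, 0.8)
  fs <- 40
  base <- make_vessel_phantom(c(32, 32), spacing = 0.4, n_branches = 0)

  one <- base
  one$values[17, 15, 1] <- 1
  src <- voxel_coordinates(one)[which(one$values > 0), , drop = FALSE]
  wp <- simulate_phantom_waveforms(geom, one, cs, pulse, sampling_rate = fs,
                                   duration = 20, time_origin = 20)
  wq <- simulate_point_waveforms(geom, src, cs, pulse, sampling_rate = fs,
                                 duration = 20, time_origin = 20)
  expect_equal(wp$samples[1, , ], wq$samples[1, , ], tolerance = 1e-9)

  two <- base
  two$values[10, 25, 1] <- 0.7
  both <- base
  both$values[17, 15, 1] <- 1
  both$values[10, 25, 1] <- 0.7
  wa <- simulate_phantom_waveforms(geom, one, cs, pulse, sampling_rate = fs,
                                   duration = 20, time_origin = 20)
  wb <- simulate_phantom_waveforms(geom, two, cs, pulse, sampling_rate = fs,
                                   duration = 20, time_origin = 20)
  wab <- simulate_phantom_waveforms(geom, both, cs, pulse, sampling_rate = fs,
                                    duration = 20, time_origin = 20)
  expect_equal(wab$samples, wa$samples + wb$samples, tolerance = 1e-12)
})
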