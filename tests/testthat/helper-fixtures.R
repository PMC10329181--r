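# Shared fixture builders. Everything is generated in code; canonical
# units are mm and us throughout.

fix_speed <- function() sound_speed(1.5)  # round value, lambda0 = 0.75 mm at 2 MHz

fix_grid <- function(pitch = 2, shape = c(3, 3, 2)) regular_grid(shape, pitch)

fix_ring <- function(n = 16, radius = 60, f0 = 2, bw = 0.8) {
  make_array_geometry("ring", radius = radius, n_elements = n,
                      center_frequency = f0, fractional_bandwidth = bw)
}

# noiseless forward ToAs for one transducer over a grid
fix_toas_one <- function(position, grid, cs) {
  apply(grid$positions, 1, function(s) predict_toa(position, s, cs))
}

# waveform set holding a given template at known integer sample offsets:
# record (m, n) is `template` delayed by offsets[m, n] samples
fix_shifted_waveforms <- function(template, offsets, sampling_rate = 40,
                                  pad = 32L) {
  m <- nrow(offsets); n <- ncol(offsets)
  tt <- length(template) + max(offsets) + pad
  x <- array(0, dim = c(m, n, tt))
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      k <- offsets[i, j]
      x[i, j, (k + 1):(k + length(template))] <- template
    }
  }
  waveform_set(x, sampling_rate = sampling_rate, time_origin = 0)
}

# sampled pulse template whose peak sits `lead` samples into the vector
fix_template <- function(pulse = pulse_model(2, 0.8), sampling_rate = 40,
                         lead = 120L) {
  tau <- (seq_len(2L * lead) - 1L - lead) / sampling_rate
  pulse_eval(pulse, tau)
}

# analytic isotropic Gaussian blob volume, sd `sigma` mm
fix_gaussian_volume <- function(sigma = 1, spacing = 0.1, half = 50L) {
  ax <- (-half:half) * spacing
  g1 <- exp(-ax^2 / (2 * sigma^2))
  vals <- outer(outer(g1, g1), g1)
  volume(vals, origin = rep(-half * spacing, 3), spacing = spacing)
}
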