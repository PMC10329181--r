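---
title: "Geometric calibration of PACT transducer arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric calibration of PACT transducer arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pactcal)
```

## The problem

Photoacoustic computed tomography (PACT) reconstructs an optical-absorption
induced initial pressure distribution from ultrasound recorded by a
transducer array surrounding the target. Reconstruction assumes the element
positions are known; manufacturing tolerances of a few hundred micrometres
-- a sizeable fraction of the acoustic wavelength -- blur reconstructions
and raise background artifacts. `pactcal` estimates the actual
three-dimensional position of every element from point-source recordings.

The measurement model is the spherical time of arrival (ToA): a point
source at stage-frame position $x'$ fires at $t = 0$ and its wavefront
reaches a transducer at $x$ at

$$ t = \lVert x - x' \rVert / c. $$

Three ingredients are unknown in principle: $x$, $x'$ and the water sound
speed $c$. Estimating all three jointly is non-convex and ill-posed (scaling
the frame and $c$ together leaves every ToA unchanged), so the package
follows the surrogate strategy: $x'$ is dictated by a calibrated 3-axis
translation stage (the stage frame *is* the coordinate system), and $c$ is
inferred from the measured water temperature.

## The pairwise linear system

Squaring the ToA relation for two sources $i, j$ and subtracting cancels
the $\lVert x \rVert^2$ term, leaving one linear equation per source pair:

$$ (x'_j - x'_i)^\top x \;=\; \tfrac12\!\left(d_i^2 - d_j^2 + r'^2_j - r'^2_i\right),
   \qquad d = c\,t,\; r'^2 = \lVert x' \rVert^2 . $$

With $M$ sources, all $\binom{M}{2}$ pairs stack into $A x = b$ with
$A \in \mathbb{R}^{N_c \times 3}$, solved per transducer by the
pseudo-inverse $\hat x = (A^\top A)^{-1} A^\top b$ (computed via the SVD).
Setting $r'_i = 0$ recovers the law of cosines, which is a useful sanity
anchor for the right-hand side. Every transducer is solved independently;
channels whose systems are rank-deficient or ill-conditioned are flagged
and keep their designed coordinates so downstream reconstruction always has
a complete coordinate set.

Numerical choices:

* canonical units are mm and µs ($c \approx 1.48$ mm/µs), keeping $A$
  entries at the grid-pitch scale and $b$ at the squared-distance scale;
* rank is declared from singular values below $10^{-8}$ of the largest;
  condition numbers above $10^4$ warn and above $10^6$ error, which flags
  nearly coplanar source grids before they corrupt estimates;
* both the full pair set and an anchored set (all pairs through one
  reference source) are available; they agree exactly on noiseless data,
  and the full set averages correlated noise at the cost of
  $O(M^2)$ rows.

## Speed of sound from temperature

`speed_from_temperature()` evaluates the fifth-order pure-water polynomial
of Marczak (valid 0--95 °C), appropriate for the deionized-water coupling
baths used in practice; salinity and pressure terms are deliberately
omitted. The inverse lookup bisects the monotone branch (0--74 °C). The
returned uncertainty is the local slope times the temperature resolution:
at 20 °C with the default 0.1 °C resolution, $\delta c \approx 0.3$ m/s.

## ToA estimation

The estimator combines noise statistics with the stereotyped shape of a
point-source response:

1. find each record's maximum (well above noise even when the first
   arrival is not);
2. align all records on their maxima and average -- with $K$ records the
   background standard deviation drops by $\sqrt K$;
3. on the averaged signal, mark the first sample exceeding
   `threshold_multiplier` (default 3) times the standard deviation of its
   pre-arrival window (default: the first 10% of samples);
4. the delay between the averaged maximum and that first arrival is a
   property of the shared pulse shape, so each record's ToA is its own
   maximum time minus this delay.

Records whose peak-to-noise ratio is below `min_snr` (default 5) are
masked invalid rather than contributing wild estimates. Maxima are located
on the raw samples (a flag switches to absolute value for
negative-leading polarities); optional three-point parabolic refinement
gives sub-sample maxima and tightens noiseless end-to-end recoveries by
roughly two orders of magnitude.

One systematic is unavoidable and documented rather than hidden: a
threshold crossing sits at the foot of the response, not at the energy
centre, so all ToAs of a set share a common offset that depends on the
pulse shape and the SNR. A shared ToA offset $\delta t$ does **not**
cancel in the pairwise differences; propagating it through the
pseudo-inverse moves the estimate by almost exactly $c\,\delta t$ along
the unit vector from the grid towards the transducer (see the error
analysis below). For the package's own simulations the offset is known --
the zero-phase kernels peak one truncated support after the measurable
onset -- and `calibrate_from_waveforms(toa_offset = pulse$support_us)`
removes it; for real data it is part of the error budget.

## Error propagation and experiment design

A measured distance perturbs as
$d_i \to d_i + t_i\,\delta c + c\,\delta t_i$, so each right-hand side
perturbs by
$\delta b = (\delta c / c)(d_i^2 - d_j^2) + c\,(d_i \delta t_i - d_j \delta t_j)$
and the position error is $P\,\delta b$ with $P = (A^\top A)^{-1}A^\top$.
`predict_position_covariance()` evaluates this first-order propagation
exactly, under two correlation models:

* **systematic_per_transducer** (default): one $\delta t$ and one
  $\delta c$ shared by all of a transducer's records. The paired terms
  reduce to $c\,\delta t\,(d_i - d_j)$, and since
  $d_i - d_j \approx \hat u^\top (x'_j - x'_i)$ (with $\hat u$ the
  grid-to-transducer direction), $P\,\delta b \approx c\,\delta t\,\hat u$:
  a *radial* displacement of magnitude $c\,\delta t$, nearly independent
  of the grid size, plus $2D\,\delta c / c$ from the speed error at
  distance $D$.
* **independent_per_measurement**: independent $\delta t_i$ per record.
  Per-axis errors then scale like
  $c\,\sigma_t\, D / (\sqrt{M}\, s_\mathrm{axis})$ with $s_\mathrm{axis}$
  the source-coordinate spread, so they shrink with more sources or a
  larger pitch and are anisotropic like the inverse grid extents.

`monte_carlo_position_error()` simulates the same error models and solves
every trial; it is the package's independent oracle for the analytic
propagation (agreement is within Monte-Carlo error, tested at 5% with
$10^4$ trials). `design_grid()` searches candidate shapes and pitches for
the smallest grid whose worst-case per-axis error meets a tolerance,
which is meaningful under the independent model (under the systematic
model the radial term is a grid-independent floor).

Two consequences deserve emphasis, because they are checked (and partly
fail) in the acceptance suite. First, with the commonly quoted budget --
0.3 m/s speed error and a ToA error of one period of a 2.25 MHz centre
frequency (0.45 µs), treated as systematic -- the dominant predicted error
is the radial $c\,\delta t \approx 0.67$ mm, which *exceeds* a
$\lambda_0/5 \approx 0.13$ mm tolerance. Standard first-order propagation
of that budget therefore cannot yield per-axis errors of a few hundredths
of a millimetre; published figures at that scale must rest on a different
(unpublished) error decomposition, e.g. treating the shared threshold
offset as a correctable bias rather than a random error. Second, under
the systematic model the anisotropy of the predicted errors follows the
transducer direction, not the grid extents; grid-extent anisotropy is the
signature of the independent model. The package reports what the stated
models actually imply and exposes both.

## The synthetic-data generator

The generator provides everything the method consumes, at the study
conditions used throughout the tests:

* **geometries**: rings (e.g. 512 elements at 100 mm), meridian arcs
  (256 elements spanning 180° of elevation, the shape of arc arrays in
  hemispherical housings; azimuthal rotations add virtual positions), and
  multi-arc hemispheres. Manufacturing error is emulated by independent
  uniform offsets in $[-0.5\lambda_0, 0.5\lambda_0]$ (375 µm at
  $c = 1500$ m/s, $f_0 = 2$ MHz) on the selected coordinates.
* **pulses**: a Gaussian one-way frequency response parameterized by
  centre frequency and one-way 6 dB fractional bandwidth. The default
  time-domain kernel is the Gaussian-modulated cosine; the
  `n_shape_bandpassed` kind is the odd, sine-modulated variant with a
  leading compression lobe -- the shape a photoacoustic point source
  actually delivers. Reconstruction-facing simulations use the N-shaped
  kind, because universal back-projection's filtered term is dominated by
  the time derivative: back-projecting an *even* kernel focuses a quarter
  period away from the source and cancels extended absorbers.
* **waveforms**: delay-and-sum of the kernel at the exact spherical ToA,
  scaled by $1/r$, with optional receive delays, per-record jitter, and
  white noise relative to the peak amplitude. Records are sized so the
  first 12% of samples precede every arrival (the estimator's default
  noise window). This is a geometric forward model, deliberately not a
  wave solver: it preserves exactly the quantities calibration consumes
  (arrival times, amplitudes, bandwidth) and omits acoustic
  heterogeneity, attenuation, dispersion, element apertures and
  directivity. Passing tests therefore validate the estimator and its
  error behaviour, not full acoustic realism.
* **phantoms**: vessel-like curvilinear branches (smoothed random walks,
  rasterized at a stated width, deterministic under a seed). The demo
  default keeps widths below the wavelength so a vessel cross-section
  reconstructs as a line-spread bump rather than a resolved, oscillatory
  interior.

## Reconstruction and metrics

`ubp_reconstruct()` implements filter-and-sum universal back-projection:
per channel the filtered term $2p(t) - 2t\,\partial p/\partial t$
(central differences, one-sided at the record ends), sampled at each
voxel's propagation time by linear interpolation and accumulated with
solid-angle weights. Weights are uniform by default (uniformly spaced
elements); `element_weights` accepts relative per-element solid angles
for layouts that tile the detection surface unevenly -- meridian arcs
sample a sphere with areal density $1/\cos(\text{elevation})$, so their
elements carry weights $\propto \cos(\text{elevation})$.

Image quality is summarized by:

* **CNR** -- (signal mean − background mean) / background standard
  deviation, with explicit ROI masks (`default_rois()` uses voxels above
  half maximum as signal and voxels beyond three times the signal
  bounding box as background);
* **size and spread** -- the squared volume, normalized, is treated as a
  3D density over voxel centres with covariance $\Sigma_{V^2}$;
  $\mathrm{size} = \sqrt{\det \Sigma_{V^2}}$ (mm³) and
  $\mathrm{spread} = \sqrt{\mathrm{tr}\, \Sigma_{V^2}}$ (mm). Both are
  axis-invariant and make no shape or polarity assumption (negative
  values are squared, not clipped). They do depend on the analysis
  region: limited-view streak background grows both metrics steadily with
  window size. The package's convention for point-target analysis,
  implemented in `point_source_study()`, is a cube of ±2 wavelengths
  around the source at $\lambda_0/16$ voxels (64³); the region dependence
  is reported alongside the metric whenever it matters.
* **FWHM** of line profiles, linearly interpolated between samples. For
  speckled images the demo takes thick profiles (averaged over ±1 mm
  along the vessel) of the image magnitude, across the local vessel
  direction -- bipolar speckle then accumulates into a wide halo instead
  of cancelling into deceptively narrow ripples.

## Study problem sizes

The bundled studies run at desk scale by design: the point-source
reconstruction study uses 512 virtual elements and a 64³ volume; the
ring-array demonstration uses 128 elements, a planar phantom and a 96²
reconstruction; Monte-Carlo verifications use $10^4$ trials on the
6×6×3 grid. Each completes in seconds to a few minutes on one CPU.

## Known limitations

* The forward model is geometric; no wave solver, no spatial impulse
  response. Strongly direction-dependent point-source responses (e.g.
  out-of-plane sources for 2D arrays) are out of scope.
* The threshold-based ToA carries a pulse-shape-dependent common offset;
  the package removes it only when the kernel is known (simulations) and
  otherwise accounts for it in the error budget.
* Joint estimation of source positions or sound speed is deliberately a
  non-goal: the linearization exists precisely because those are fixed by
  surrogate measurements.
* Size/spread values are comparable only at a stated analysis region.
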