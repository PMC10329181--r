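#' Sampled point-source waveform set
#'
#' Container for M x N x T sampled pressure signals (M point-source
#' positions, N transducer channels, T time samples) plus sampling
#' metadata. Sample k of every trace corresponds to the time
#' `time_origin + (k - 1) / sampling_rate` (us) after laser emission.
#'
#' @param samples numeric M x N x T array (arbitrary pressure units).
#' @param sampling_rate sampling rate, MHz.
#' @param time_origin time of sample 1 relative to laser emission, us.
#' @param receive_delays optional N-vector of per-channel delays, us.
#' @return an object of class `waveform_set`.
#' @export
waveform_set <- function(samples, sampling_rate, time_origin = 0,
                         receive_delays = NULL) {
  stopifnot(is.array(samples), length(dim(samples)) == 3L)
  if (dim(samples)[3] < 16L) {
    stop("invalid input: waveform records need at least 16 samples",
         call. = FALSE)
  }
  .assert_finite(samples, "samples")
  stopifnot(length(sampling_rate) == 1L, is.finite(sampling_rate),
            sampling_rate > 0, is.finite(time_origin))
  n <- dim(samples)[2]
  if (!is.null(receive_delays)) {
    stopifnot(length(receive_delays) == n)
    .assert_finite(receive_delays, "receive_delays")
  }
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 time_origin = time_origin,
                 receive_delays = receive_delays),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(paste0("<waveform_set> %d sources x %d channels x %d samples, ",
                     "%g MHz, t0 = %g us\n"),
              d[1], d[2], d[3], x$sampling_rate, x$time_origin))
  invisible(x)
}

#' Time axis of a waveform set
#' @param waveforms a [waveform_set].
#' @return numeric T-vector of sample times, us.
#' @export
waveform_times <- function(waveforms) {
  waveforms$time_origin +
    (seq_len(dim(waveforms$samples)[3]) - 1) / waveforms$sampling_rate
}

#' Estimate times of arrival from point-source waveforms
#'
#' Hybrid estimator combining noise statistics with the stereotyped shape
#' of the point-source response:
#' \enumerate{
#'   \item locate the maximum of every record (raw signal; optionally its
#'     absolute value);
#'   \item align the records on their maxima and average them, which boosts
#'     the SNR by roughly the square root of the number of records;
#'   \item on the averaged signal, take the first sample exceeding
#'     `threshold_multiplier` times the standard deviation of its
#'     pre-arrival noise window as the averaged first arrival;
#'   \item the delay between the averaged maximum and the averaged first
#'     arrival is a property of the (shared) pulse shape, so the per-record
#'     ToA is the time of that record's maximum minus this delay.
#' }
#' Records whose peak-to-noise ratio falls below `min_snr` do not enter the
#' average and are masked invalid in the output.
#'
#' @param waveforms a [waveform_set].
#' @param threshold_multiplier threshold in units of the noise standard
#'   deviation of the averaged signal (default 3).
#' @param noise_window integer vector of sample indices known to precede
#'   every arrival; default the first 10\% of samples.
#' @param min_snr validity threshold on peak / noise-sd per record
#'   (default 5).
#' @param polarity `"positive"` to locate maxima on the raw signal
#'   (default), `"abs"` to use the absolute value.
#' @param grouping `"pooled"` averages all M x N records together
#'   (default); `"per_transducer"` forms one average per channel.
#' @param refine `"none"` (integer-sample maxima, default) or
#'   `"parabolic"` for three-point sub-sample refinement of each maximum.
#' @return a [toa_matrix] (M x N) with attributes `delay_us` (the
#'   maximum-to-first-arrival delay per group) and `snr` (M x N peak/noise).
#' @export
estimate_toas <- function(waveforms, threshold_multiplier = 3,
                          noise_window = NULL, min_snr = 5,
                          polarity = c("positive", "abs"),
                          grouping = c("pooled", "per_transducer"),
                          refine = c("none", "parabolic")) {
  polarity <- match.arg(polarity)
  grouping <- match.arg(grouping)
  refine <- match.arg(refine)
  stopifnot(inherits(waveforms, "waveform_set"))
  x <- waveforms$samples
  d <- dim(x); m <- d[1]; n <- d[2]; tt <- d[3]
  fs <- waveforms$sampling_rate
  if (is.null(noise_window)) noise_window <- seq_len(max(2L, floor(0.1 * tt)))
  noise_window <- as.integer(noise_window)
  if (length(noise_window) < 2L || any(noise_window < 1L | noise_window > tt)) {
    stop("invalid input: empty or out-of-range noise window", call. = FALSE)
  }

  sig <- if (polarity == "abs") abs(x) else x
  flat <- matrix(aperm(sig, c(3, 1, 2)), nrow = tt)  # T x (M*N), source-major
  kmax <- max.col(t(flat), ties.method = "first")
  peak <- flat[cbind(kmax, seq_len(m * n))]
  nsd <- apply(flat[noise_window, , drop = FALSE], 2, stats::sd)
  snr <- ifelse(nsd > 0, peak / nsd, Inf)
  ok <- is.finite(peak) & peak > 0 & snr >= min_snr

  if (!any(ok)) {
    stop("estimation failure: no record exceeds min_snr = ", min_snr,
         call. = FALSE)
  }

  # flattened record index = (channel - 1) * M + source
  group_of <- if (grouping == "pooled") rep(1L, m * n) else rep(seq_len(n), each = m)
  delay_us <- rep(NA_real_, max(group_of))
  for (g in unique(group_of)) {
    idx <- which(ok & group_of == g)
    if (!length(idx)) next
    # common aligned window around the maxima
    lo <- -min(kmax[idx] - 1L)
    hi <- min(tt - kmax[idx])
    if (hi - lo < 8L) next
    tau <- lo:hi
    avg <- rowMeans(vapply(idx, function(i) flat[kmax[i] + tau, i],
                           numeric(length(tau))))
    nw <- seq_len(max(2L, floor(0.1 * length(tau))))
    nse <- stats::sd(avg[nw])
    thr <- threshold_multiplier * nse
    cross <- which(avg > thr)
    cross <- cross[cross <= which.max(avg)]
    if (!length(cross)) {
      stop("estimation failure: averaged signal never exceeds the noise threshold",
           call. = FALSE)
    }
    toa_tau <- tau[cross[1]]
    delay_us[g] <- (0 - toa_tau) / fs  # averaged max sits at tau = 0
  }
  if (all(is.na(delay_us))) {
    stop("estimation failure: no group had enough aligned samples", call. = FALSE)
  }

  kfrac <- rep(0, m * n)
  if (refine == "parabolic") {
    inb <- kmax > 1L & kmax < tt
    i3 <- which(ok & inb)
    y0 <- flat[cbind(kmax[i3] - 1L, i3)]
    y1 <- flat[cbind(kmax[i3], i3)]
    y2 <- flat[cbind(kmax[i3] + 1L, i3)]
    den <- y0 - 2 * y1 + y2
    kfrac[i3] <- ifelse(abs(den) > 0, 0.5 * (y0 - y2) / den, 0)
    kfrac <- pmax(pmin(kfrac, 0.5), -0.5)
  }

  tmax <- waveforms$time_origin + (kmax - 1 + kfrac) / fs
  toa <- tmax - delay_us[group_of]
  ok <- ok & is.finite(toa) & toa > 0
  toa[!ok] <- NA_real_
  times <- matrix(toa, nrow = m, ncol = n)
  out <- toa_matrix(times, matrix(ok, nrow = m, ncol = n))
  attr(out, "delay_us") <- delay_us
  attr(out, "snr") <- matrix(snr, nrow = m, ncol = n)
  out
}
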