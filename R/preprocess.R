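#' Polynomial detrending
#'
#' Removes the least-squares polynomial trend (default cubic) from a signal.
#' This is the first conditioning step applied to every channel before
#' spectral analysis, so that slow drifts do not leak into the lowest
#' frequency bands.
#'
#' @param ts A [time_series].
#' @param order Polynomial order (default 3).
#' @return A [time_series] equal to the input minus its best-fit polynomial;
#'   `fs`, `label`, `t0` preserved.
#' @examples
#' t <- seq(0, 100, by = 0.1)
#' ts <- time_series(sin(2 * pi * 0.2 * t) + 0.01 * t, fs = 10)
#' dt <- detrend_poly(ts)
#' @export
detrend_poly <- function(ts, order = 3L) {
  stopifnot(inherits(ts, "time_series"))
  order <- as.integer(order)
  if (order < 0L) stop("`order` must be non-negative", call. = FALSE)
  n <- length(ts$samples)
  if (n <= order + 1L)
    stop(sprintf("cannot fit order-%d polynomial to %d samples", order, n),
         call. = FALSE)
  if (order == 0L) {
    res <- ts$samples - mean(ts$samples)
  } else {
    # orthogonal polynomial basis: numerically stable at high sample counts
    tt <- seq_len(n)
    fit <- stats::lm.fit(cbind(1, stats::poly(tt, order)), ts$samples)
    res <- fit$residuals
  }
  time_series(res, ts$fs, ts$label, ts$t0, ts$units)
}

# symmetric (even) reflection padding before zero-phase filtering: unlike
# anti-symmetric reflection it introduces no step in the local mean, so the
# slow high-pass corner sees no spurious low-frequency edge transient
.reflect_pad <- function(x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  head_pad <- x[seq(npad + 1L, 2L, by = -1L)]
  tail_pad <- x[seq(n - 1L, n - npad, by = -1L)]
  list(x = c(head_pad, x, tail_pad), npad = npad)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Forward-backward (zero net phase shift) Butterworth bandpass filtering
#' with odd-reflection padding at the edges. The default band 0.005-2 Hz
#' covers the cardiovascular oscillation range; each pass uses an order-2
#' design, so the effective magnitude response is order 4.
#'
#' @param ts A [time_series].
#' @param f_lo,f_hi Band corners in Hz; `0 < f_lo < f_hi < fs/2`.
#' @param order Per-pass Butterworth order (default 2).
#' @return Filtered [time_series], same length, `fs` and `label`.
#' @examples
#' t <- seq(0, 500, by = 0.05)
#' ts <- time_series(sin(2 * pi * 0.1 * t), fs = 20)
#' bp <- bandpass_zerophase(ts)
#' @export
bandpass_zerophase <- function(ts, f_lo = 0.005, f_hi = 2, order = 2L) {
  stopifnot(inherits(ts, "time_series"))
  nyq <- ts$fs / 2
  if (!(f_lo > 0 && f_lo < f_hi))
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi >= nyq)
    stop(sprintf("upper corner %g Hz is at or above Nyquist (%g Hz)",
                 f_hi, nyq), call. = FALSE)
  # cascade of high- and low-pass sections: a single transfer-function
  # bandpass with corners nearly three decades apart is numerically
  # ill-conditioned, the cascade is not
  bh <- signal::butter(order, f_lo / nyq, type = "high")
  bl <- signal::butter(order, f_hi / nyq, type = "low")
  # pad by roughly one settling length of the slow corner
  npad <- ceiling(3 * ts$fs / f_lo)
  p <- .reflect_pad(ts$samples, npad)
  y <- signal::filtfilt(bl, signal::filtfilt(bh, p$x))
  y <- y[(p$npad + 1L):(p$npad + length(ts$samples))]
  time_series(y, ts$fs, ts$label, ts$t0, ts$units)
}

# linear convolution: direct FIR when cheap, power-of-2 FFT otherwise
# (stats::convolve FFTs at the raw output length, which can have large
# prime factors and degrade badly)
.fir_conv <- function(x, h) {
  n_out <- length(x) + length(h) - 1L
  if (as.double(length(x)) * length(h) < 3e7) {
    y <- stats::filter(c(x, numeric(length(h))), h,
                       method = "convolution", sides = 1L)
    as.numeric(y)[seq_len(n_out)]
  } else {
    nfft <- stats::nextn(n_out, 2)
    y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                         stats::fft(c(h, numeric(nfft - length(h)))),
                       inverse = TRUE)) / nfft
    y[seq_len(n_out)]
  }
}

# best rational approximation p/q to ratio r with bounded denominator
.rationalize <- function(r, max_den = 4096L) {
  best <- c(1L, 1L); best_err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) {
      best <- c(as.integer(p), as.integer(q)); best_err <- err
      if (err < 1e-12) break
    }
  }
  best
}

#' Resample a time series
#'
#' Rational-ratio polyphase resampling with FIR anti-alias filtering
#' (downsampling never aliases), preserving event timing -- important for
#' ECG pulse trains. Edges are odd-reflection padded so that boundary
#' transients of the anti-alias filter do not distort the record.
#'
#' @param ts A [time_series].
#' @param fs_new Target sampling frequency in Hz.
#' @return A [time_series] at `fs_new`.
#' @export
resample_ts <- function(ts, fs_new) {
  stopifnot(inherits(ts, "time_series"))
  if (!is.numeric(fs_new) || length(fs_new) != 1L || !is.finite(fs_new) ||
      fs_new <= 0)
    stop("`fs_new` must be a single positive number", call. = FALSE)
  if (isTRUE(all.equal(fs_new, ts$fs)))
    return(time_series(ts$samples, fs_new, ts$label, ts$t0, ts$units))
  pq <- .rationalize(fs_new / ts$fs)
  p <- pq[1L]; q <- pq[2L]
  n <- length(ts$samples)
  m <- max(p, q)
  taps <- 20L * m                         # even order -> integer group delay
  npad <- min(n - 1L, ceiling(taps / p) + q)
  pd <- .reflect_pad(ts$samples, npad)
  # zero-stuff by p, lowpass at the tighter of the two Nyquists, keep
  # every q-th sample; FIR gain p restores amplitude
  up <- numeric(length(pd$x) * p)
  up[seq(1L, length(up), by = p)] <- pd$x
  h <- p * signal::fir1(taps, 1 / m, type = "low")
  y_full <- .fir_conv(up, h)
  n_out <- floor((n - 1L) * p / q) + 1L
  idx <- pd$npad * p + (0:(n_out - 1L)) * q + taps / 2L + 1L
  y <- y_full[idx]
  time_series(y, ts$fs * p / q, ts$label, ts$t0, ts$units)
}

#' Remove the cardiac cross-talk mode from an EEG channel
#'
#' Electrical cross-talk from the heart contaminates low-frequency EEG.
#' This routine extracts the maximum-amplitude ridge of the channel's
#' wavelet transform inside the cardiac band, reconstructs that single
#' oscillatory mode from the ridge coefficients (amplitude and phase at the
#' ridge; harmonics are not modelled), and subtracts it. If no ridge stands
#' out above the in-band amplitude floor the input is returned unchanged
#' with a warning.
#'
#' @param eeg A bandpassed EEG [time_series].
#' @param cardiac_band Length-2 numeric, Hz (default `c(0.6, 1.7)`).
#' @param f0 Wavelet frequency-resolution parameter for the cardiac-band
#'   transform (default 2: narrow frequency response suits ridge tracking).
#' @param voices Grid density, voices per octave.
#' @param ridge_floor Ridge acceptance factor: the median ridge amplitude
#'   must exceed `ridge_floor` times the median in-band amplitude.
#' @return A [time_series] with the cardiac mode subtracted.
#' @export
remove_cardiac_artifact <- function(eeg, cardiac_band = c(0.6, 1.7),
                                    f0 = 2, voices = 32L,
                                    ridge_floor = 2) {
  stopifnot(inherits(eeg, "time_series"), length(cardiac_band) == 2L)
  if (cardiac_band[2L] >= eeg$fs / 2)
    stop("cardiac band extends to or beyond Nyquist", call. = FALSE)
  wt <- morlet_wt(eeg, fmin = cardiac_band[1L], fmax = cardiac_band[2L],
                  f0 = f0, voices = voices)
  rg <- extract_ridge(wt, cardiac_band)
  amp <- Mod(wt$coeffs)
  med_band <- stats::median(amp[amp > 0])
  if (stats::median(rg$amp_track) <= ridge_floor * med_band) {
    warning("no cardiac ridge above the in-band amplitude floor; ",
            "returning input unchanged", call. = FALSE)
    return(eeg)
  }
  mode <- Re(wt$coeffs[cbind(rg$index_track, seq_along(rg$index_track))])
  time_series(eeg$samples - mode, eeg$fs, eeg$label, eeg$t0, eeg$units)
}

#' Per-signal-class preprocessing profiles
#'
#' Default conditioning parameters per modality: bandpass corners and the
#' analysis resampling target. The slow corner is always 0.005 Hz; fNIRS
#' and EEG are analysed up to 4 Hz (capped at 0.45 fs), other classes to
#' 2 Hz.
#'
#' @param class One of `"fnirs"`, `"eeg"`, `"ecg"`, `"respiration"`,
#'   `"rate"`.
#' @param fs Sampling frequency of the channel, Hz.
#' @return List with `f_lo`, `f_hi`, `fs_analysis`.
#' @export
preprocess_profile <- function(class = c("fnirs", "eeg", "ecg",
                                         "respiration", "rate"),
                               fs) {
  class <- match.arg(class)
  switch(class,
    fnirs = list(f_lo = 0.005, f_hi = min(4, 0.45 * fs), fs_analysis = fs),
    eeg   = list(f_lo = 0.005, f_hi = min(4, 0.45 * fs), fs_analysis = 31.25),
    ecg         = list(f_lo = 0.005, f_hi = min(2, 0.45 * fs), fs_analysis = 100),
    respiration = list(f_lo = 0.005, f_hi = min(2, 0.45 * fs), fs_analysis = 100),
    rate        = list(f_lo = 0.005, f_hi = min(2, 0.45 * fs), fs_analysis = 20)
  )
}
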