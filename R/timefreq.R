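#' Logarithmic frequency grid
#'
#' Frequencies spaced by a constant ratio `2^(1/voices)`, covering
#' `[fmin, fmax]`. Slow physiological oscillations span more than two
#' decades (periods from under a second to several minutes), so analysis
#' grids are logarithmic throughout the package.
#'
#' @param fmin,fmax Grid limits in Hz.
#' @param voices Voices per octave (grid points per frequency doubling).
#' @return Object of class `freq_grid`: list with `freqs` (Hz, strictly
#'   increasing, constant ratio) and `voices`.
#' @export
freq_grid <- function(fmin, fmax, voices = 32L) {
  if (!(fmin > 0 && fmax > fmin)) stop("need 0 < fmin < fmax", call. = FALSE)
  voices <- as.integer(voices)
  if (voices < 1L) stop("`voices` must be >= 1", call. = FALSE)
  k <- 0:floor(voices * log2(fmax / fmin) + 1e-9)
  structure(list(freqs = fmin * 2^(k / voices), voices = voices),
            class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %d frequencies, %g-%g Hz, %d voices/octave\n",
              length(x$freqs), min(x$freqs), max(x$freqs), x$voices))
  invisible(x)
}

# cache of Morlet frequency-domain weight matrices, keyed by parameter hash.
# Cohort analyses transform hundreds of equal-length channels; the weights
# depend only on (nfft, fs, grid, f0) and dominate setup cost.
.wt_cache <- new.env(parent = emptyenv())

.morlet_weights <- function(nfft, fs, freqs, f0) {
  key <- paste(nfft, fs, f0, length(freqs), freqs[1L], freqs[length(freqs)],
               sep = "|")
  hit <- .wt_cache[[key]]
  if (!is.null(hit)) return(hit)
  fk <- (seq_len(nfft) - 1L) / nfft * fs       # 0 .. fs(1-1/nfft)
  pos <- fk <= fs / 2                           # analytic: keep f >= 0 only
  corr <- exp(-(2 * pi * f0)^2 / 2)             # admissibility correction
  W <- matrix(0, nfft, length(freqs))
  for (j in seq_along(freqs)) {
    sf <- (f0 / freqs[j]) * fk[pos]
    # normalized so a unit-amplitude sinusoid has ridge amplitude 1
    W[pos, j] <- 2 * (exp(-2 * pi^2 * (sf - f0)^2) -
                        corr * exp(-2 * pi^2 * sf^2))
  }
  if (length(.wt_cache) > 16L) rm(list = ls(.wt_cache), envir = .wt_cache)
  .wt_cache[[key]] <- W
  W
}

#' Morlet continuous wavelet transform
#'
#' Continuous wavelet transform with the (admissibility-corrected) Morlet
#' mother wavelet on a logarithmic frequency grid. The wavelet is
#' normalized so that the ridge amplitude of a stationary unit-amplitude
#' sinusoid equals 1 (proportionality constant 1), matching the
#' amplitude-then-square power convention of [time_avg_power()]. Transforms
#' are computed in the frequency domain with zero padding; coefficients
#' within `sqrt(2) * f0 / f` seconds of either record edge (the e-folding
#' width of the Gaussian envelope) are flagged as edge-affected by the cone
#' of influence.
#'
#' @param ts A [time_series].
#' @param fmin,fmax Frequency range in Hz; `fmax` defaults to the smaller
#'   of 2 Hz and 0.45 fs and must not exceed fs/2.
#' @param f0 Frequency-resolution parameter (dimensionless, default 1).
#'   Larger values narrow the frequency response at the cost of time
#'   resolution.
#' @param voices Voices per octave for the grid (default 32).
#' @return Object of class `wavelet_transform`: list with `coeffs`
#'   (complex, frequency x time), `grid` ([freq_grid]), `fs`, `f0`, `t0`,
#'   `label` and `coi_halfwidth` (per-frequency edge exclusion, seconds).
#' @seealso [coi_mask()], [time_avg_power()], [instantaneous_phase()]
#' @export
morlet_wt <- function(ts, fmin = 0.005, fmax = NULL, f0 = 1, voices = 32L) {
  stopifnot(inherits(ts, "time_series"))
  if (is.null(fmax)) fmax <- min(2, 0.45 * ts$fs)
  if (!(fmin > 0 && fmin < fmax)) stop("need 0 < fmin < fmax", call. = FALSE)
  if (fmax > ts$fs / 2)
    stop(sprintf("fmax = %g Hz exceeds Nyquist (%g Hz)", fmax, ts$fs / 2),
         call. = FALSE)
  n <- length(ts$samples)
  dur <- n / ts$fs
  if (dur < 1 / fmin)
    stop(sprintf(paste0("record of %.1f s is shorter than one period of ",
                        "fmin = %g Hz"), dur, fmin), call. = FALSE)
  if (dur <= 2 * sqrt(2) * f0 / fmin)
    stop(sprintf(paste0("record of %.1f s leaves no edge-unaffected ",
                        "coefficients at fmin = %g Hz (needs > %.1f s)"),
                 dur, fmin, 2 * sqrt(2) * f0 / fmin), call. = FALSE)
  grid <- freq_grid(fmin, fmax, voices)
  pad <- ceiling(sqrt(2) * f0 / fmin * ts$fs)
  nfft <- stats::nextn(n + pad, 2)
  xf <- stats::fft(c(ts$samples, numeric(nfft - n)))
  W <- .morlet_weights(nfft, ts$fs, grid$freqs, f0)
  co <- stats::mvfft(W * xf, inverse = TRUE) / nfft
  co <- t(co[seq_len(n), , drop = FALSE])      # frequency x time
  structure(
    list(coeffs = co, grid = grid, fs = ts$fs, f0 = f0, t0 = ts$t0,
         label = ts$label, coi_halfwidth = sqrt(2) * f0 / grid$freqs),
    class = "wavelet_transform"
  )
}

#' @export
print.wavelet_transform <- function(x, ...) {
  cat(sprintf(paste0("<wavelet_transform> %s: %d freqs x %d times, ",
                     "%g-%g Hz, f0 = %g\n"),
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$coeffs), ncol(x$coeffs),
              min(x$grid$freqs), max(x$grid$freqs), x$f0))
  invisible(x)
}

#' Cone-of-influence mask of a wavelet transform
#'
#' @param wt A `wavelet_transform`.
#' @return Logical matrix (frequency x time); `TRUE` marks coefficients
#'   unaffected by record edges. The valid region shrinks towards low
#'   frequencies.
#' @export
coi_mask <- function(wt) {
  stopifnot(inherits(wt, "wavelet_transform"))
  nt <- ncol(wt$coeffs)
  tt <- (seq_len(nt) - 1L) / wt$fs
  edge <- pmin(tt, tt[nt] - tt)                 # distance to nearest edge, s
  outer(wt$coi_halfwidth, edge, FUN = "<")
}

# per-frequency column index range inside the COI (NULL row if none)
.coi_range <- function(wt) {
  nt <- ncol(wt$coeffs)
  lo <- floor(wt$coi_halfwidth * wt$fs) + 2L    # first strictly inside
  hi <- nt - lo + 1L
  cbind(lo = lo, hi = hi)
}

#' Time-averaged wavelet power
#'
#' The per-frequency power is the square of the time-averaged coefficient
#' amplitude, `(mean |W|)^2`, taken over edge-unaffected times. The
#' mean-of-squares convention `mean(|W|^2)` is available via
#' `convention = "energy"` but is not the default.
#'
#' @param wt A `wavelet_transform`.
#' @param use_coi If `TRUE` (default) average only inside the cone of
#'   influence; frequencies with no valid samples get `NA`.
#' @param convention `"amplitude"` (default) or `"energy"`.
#' @return Object of class `power_spectrum`: list with `power`, `grid`,
#'   `n_times` (valid samples per frequency).
#' @export
time_avg_power <- function(wt, use_coi = TRUE,
                           convention = c("amplitude", "energy")) {
  stopifnot(inherits(wt, "wavelet_transform"))
  convention <- match.arg(convention)
  nf <- nrow(wt$coeffs); nt <- ncol(wt$coeffs)
  rng <- .coi_range(wt)
  power <- rep(NA_real_, nf)
  n_times <- integer(nf)
  for (k in seq_len(nf)) {
    idx <- if (use_coi) {
      if (rng[k, "lo"] > rng[k, "hi"]) integer(0)
      else rng[k, "lo"]:rng[k, "hi"]
    } else seq_len(nt)
    n_times[k] <- length(idx)
    if (!length(idx)) next
    a <- Mod(wt$coeffs[k, idx])
    power[k] <- if (convention == "amplitude") mean(a)^2 else mean(a^2)
  }
  structure(list(power = power, grid = wt$grid, n_times = n_times,
                 label = wt$label, convention = convention),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s: %d frequencies, %g-%g Hz\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$power), min(x$grid$freqs), max(x$grid$freqs)))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, ...) {
  graphics::plot(x$grid$freqs, x$power, type = "l", log = "x",
                 xlab = "Frequency (Hz)", ylab = "Time-averaged power",
                 main = x$label, ...)
  invisible(x)
}

#' Instantaneous phase field of a wavelet transform
#'
#' @param wt A `wavelet_transform`.
#' @param amp_tol Amplitudes below `amp_tol` times the transform maximum
#'   have no meaningful phase and are flagged invalid (default `1e-12`).
#' @return Object of class `phase_field`: list with `phase` (radians in
#'   `(-pi, pi]`, frequency x time, `NA` where invalid), `valid` (logical
#'   matrix combining the amplitude flag and the cone of influence),
#'   `grid`, `fs`.
#' @export
instantaneous_phase <- function(wt, amp_tol = 1e-12) {
  stopifnot(inherits(wt, "wavelet_transform"))
  amp <- Mod(wt$coeffs)
  ok <- amp > amp_tol * max(amp, 0)
  ph <- Arg(wt$coeffs)
  ph[!ok] <- NA_real_
  structure(list(phase = ph, valid = ok & coi_mask(wt), grid = wt$grid,
                 fs = wt$fs, label = wt$label),
            class = "phase_field")
}

#' Extract an amplitude ridge from a wavelet transform
#'
#' Greedy maximum tracking with a continuity penalty: at each time step the
#' in-band frequency maximizing `|W| - lambda * (grid steps from previous
#' pick)` is chosen, walking outwards from the global in-band maximum. The
#' default penalty (5% of the in-band amplitude maximum per grid step)
#' suppresses jumps of more than about 3 grid steps per sample unless the
#' amplitude advantage is substantial.
#'
#' @param wt A `wavelet_transform`.
#' @param band Length-2 numeric, Hz; must contain at least one grid point.
#' @param lambda Continuity penalty per grid step (amplitude units);
#'   default `0.05 * max in-band amplitude`.
#' @return Object of class `ridge`: list with `freq_track` (Hz),
#'   `amp_track`, `index_track` (row indices into `wt$coeffs`), `band`,
#'   `fs`, `t0`.
#' @export
extract_ridge <- function(wt, band, lambda = NULL) {
  stopifnot(inherits(wt, "wavelet_transform"), length(band) == 2L)
  rows <- which(wt$grid$freqs >= band[1L] & wt$grid$freqs <= band[2L])
  if (!length(rows))
    stop(sprintf("no grid frequency inside band [%g, %g] Hz",
                 band[1L], band[2L]), call. = FALSE)
  A <- Mod(wt$coeffs[rows, , drop = FALSE])
  nb <- nrow(A); nt <- ncol(A)
  if (is.null(lambda)) lambda <- 0.05 * max(A)
  ks <- seq_len(nb)
  pick <- integer(nt)
  t_star <- which.max(apply(A, 2L, max))
  pick[t_star] <- which.max(A[, t_star])
  if (t_star < nt) for (t in (t_star + 1L):nt)
    pick[t] <- which.max(A[, t] - lambda * abs(ks - pick[t - 1L]))
  if (t_star > 1L) for (t in (t_star - 1L):1L)
    pick[t] <- which.max(A[, t] - lambda * abs(ks - pick[t + 1L]))
  # unpenalized re-maximization within +/-3 grid steps of the smooth track:
  # removes the hysteresis the penalty causes on sweeping frequencies while
  # keeping large jumps suppressed
  for (t in seq_len(nt)) {
    w <- max(1L, pick[t] - 3L):min(nb, pick[t] + 3L)
    pick[t] <- w[which.max(A[w, t])]
  }
  structure(
    list(freq_track = wt$grid$freqs[rows][pick],
         amp_track = A[cbind(pick, seq_len(nt))],
         index_track = rows[pick], band = as.numeric(band),
         fs = wt$fs, t0 = wt$t0, label = wt$label),
    class = "ridge"
  )
}

#' Average a spectral curve over a frequency band
#'
#' Arithmetic mean over grid frequencies `f` with
#' `band[1] <= f < band[2]` (half-open), excluding missing values. Used to
#' reduce power and coherence spectra to one value per band per subject.
#'
#' @param x A `power_spectrum`, `coherence_spectrum`, or numeric vector.
#' @param band Length-2 numeric, Hz, or a row name of [frequency_bands()].
#' @param freqs Grid frequencies (Hz); required when `x` is a bare vector.
#' @return Scalar band mean (`NA` if every in-band value is missing).
#' @export
band_average <- function(x, band, freqs = NULL) {
  if (is.character(band) && length(band) == 1L) {
    fb <- frequency_bands()
    row <- fb[fb$band == band, ]
    if (!nrow(row)) stop("unknown band name: ", band, call. = FALSE)
    band <- c(row$fmin, row$fmax)
  }
  stopifnot(length(band) == 2L, band[1L] < band[2L])
  if (inherits(x, "power_spectrum")) {
    freqs <- x$grid$freqs; vals <- x$power
  } else if (inherits(x, "coherence_spectrum")) {
    freqs <- x$grid$freqs; vals <- x$wpc
  } else if (inherits(x, "effective_coherence")) {
    freqs <- x$grid$freqs; vals <- x$effective
  } else {
    if (is.null(freqs))
      stop("`freqs` required for a bare numeric curve", call. = FALSE)
    vals <- as.numeric(x)
    stopifnot(length(vals) == length(freqs))
  }
  sel <- freqs >= band[1L] & freqs < band[2L]
  if (!any(sel))
    stop(sprintf("no grid frequency in band [%g, %g) Hz", band[1L], band[2L]),
         call. = FALSE)
  v <- vals[sel]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Cardiovascular frequency bands
#'
#' The six canonical frequency intervals of cardiovascular oscillations and
#' their physiological attribution: endothelial (non-NO and NO dependent),
#' neurogenic (autonomic modulation of smooth muscle), myogenic (pressure-
#' reactive smooth muscle tone), respiration, and cardiac.
#'
#' @return `data.frame` with columns `band`, `fmin`, `fmax` (Hz).
#' @export
frequency_bands <- function() {
  data.frame(
    band = c("endothelial", "endothelial_NO", "neurogenic", "myogenic",
             "respiration", "cardiac"),
    fmin = c(0.005, 0.0095, 0.021, 0.052, 0.145, 0.6),
    fmax = c(0.0095, 0.021, 0.052, 0.145, 0.6, 1.7),
    stringsAsFactors = FALSE
  )
}

#' Default wavelet parameters per analysis class
#'
#' Per-signal-class `(fmin, fmax, f0, fs)` tuples used throughout the
#' pipeline: fNIRS/EEG power and coherence are analysed over 0.005-4 Hz at
#' 31.25 Hz with `f0 = 1`; heart-ridge extraction uses `f0 = 2` over
#' 0.6-2 Hz at 100 Hz; respiration-ridge extraction 0.1-0.6 Hz; rate-series
#' (IHR/IRR) analyses run over 0.005-2 Hz at 20 Hz.
#'
#' @param class One of `"fnirs"`, `"eeg"`, `"heart_ridge"`, `"resp_ridge"`,
#'   `"rate"`.
#' @return List with `fmin`, `fmax`, `f0`, `fs`.
#' @export
wt_params <- function(class = c("fnirs", "eeg", "heart_ridge", "resp_ridge",
                                "rate")) {
  class <- match.arg(class)
  switch(class,
    fnirs       = list(fmin = 0.005, fmax = 4,   f0 = 1, fs = 31.25),
    eeg         = list(fmin = 0.005, fmax = 4,   f0 = 1, fs = 31.25),
    heart_ridge = list(fmin = 0.6,   fmax = 2,   f0 = 2, fs = 100),
    resp_ridge  = list(fmin = 0.1,   fmax = 0.6, f0 = 1, fs = 100),
    rate        = list(fmin = 0.005, fmax = 2,   f0 = 1, fs = 20)
  )
}
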