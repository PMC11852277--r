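#' Uniformly sampled time series
#'
#' Lightweight container for a single uniformly sampled signal. All
#' preprocessing and time-frequency functions in the package consume and
#' return `time_series` objects.
#'
#' @param samples Numeric vector of signal values (arbitrary units).
#' @param fs Sampling frequency in Hz; must be positive and finite.
#' @param label Channel name, e.g. `"N3"`, `"Fp1"`, `"ECG"`.
#' @param t0 Start time of the first sample in seconds (default 0).
#' @param units Free-text unit string carried through for reporting.
#'
#' @return An object of class `time_series`: a list with elements
#'   `samples`, `fs`, `label`, `t0`, `units`.
#' @examples
#' ts <- time_series(sin(2 * pi * 0.1 * seq(0, 60, by = 0.05)), fs = 20,
#'                   label = "demo")
#' ts
#' @export
time_series <- function(samples, fs, label = "", t0 = 0, units = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive finite number", call. = FALSE)
  if (length(samples) < 2L)
    stop("`samples` must contain at least 2 values", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("`samples` must be finite", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, label = as.character(label)[1L],
         t0 = as.numeric(t0)[1L], units = as.character(units)[1L]),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %s: %d samples @ %g Hz (%.1f s)%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' Sample times of a time series
#'
#' @param ts A [time_series].
#' @return Numeric vector of times in seconds (`t0 + (0:(n-1))/fs`).
#' @export
ts_times <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + (seq_along(ts$samples) - 1) / ts$fs
}

#' Duration of a time series in seconds
#' @param ts A [time_series].
#' @return Record duration `n / fs` in seconds.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$fs

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time = ts_times(x), value = x$samples)
}

#' Truncate a time series to a time window
#'
#' Used to cut all modalities of one subject to a common analysis window
#' before coherence analysis.
#'
#' @param ts A [time_series].
#' @param duration Window length in seconds.
#' @param offset Window start relative to the record start, seconds.
#' @return A [time_series] covering `[offset, offset + duration]`.
#' @export
ts_window <- function(ts, duration, offset = 0) {
  stopifnot(inherits(ts, "time_series"), duration > 0, offset >= 0)
  i0 <- 1L + round(offset * ts$fs)
  i1 <- min(length(ts$samples), i0 + round(duration * ts$fs) - 1L)
  if (i1 - i0 + 1L < 2L)
    stop("window selects fewer than 2 samples", call. = FALSE)
  time_series(ts$samples[i0:i1], ts$fs, ts$label,
              t0 = ts$t0 + (i0 - 1L) / ts$fs, units = ts$units)
}
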