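# shared fixture builders; everything is generated in code at test time

# sinusoid as a time_series
sine_ts <- function(freq, fs, duration, amp = 1, phase = 0, label = "") {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  time_series(amp * sin(2 * pi * freq * t + phase), fs, label)
}

# Gaussian pulse train (ECG-like) sampled at fs
pulse_train_ts <- function(peak_times, fs, duration, width = 0.02,
                           noise = 0, seed = 1) {
  set.seed(seed)
  n <- round(duration * fs)
  tg <- (0:(n - 1)) / fs
  x <- if (noise > 0) rnorm(n, sd = noise) else numeric(n)
  for (p in peak_times) {
    i <- round(p * fs) + 1L
    idx <- max(1L, i - ceiling(5 * width * fs)):min(n, i + ceiling(5 * width * fs))
    x[idx] <- x[idx] + exp(-(tg[idx] - p)^2 / (2 * width^2))
  }
  time_series(x, fs, "pulse")
}

# phase-randomized noise: amplitude spectrum of white noise, random phases
phase_randomized_noise <- function(n, fs, seed) {
  set.seed(seed)
  xf <- fft(rnorm(n))
  k <- seq_len(n)
  ph <- runif(n, -pi, pi)
  xf2 <- Mod(xf) * exp(1i * ph)
  Re(fft(xf2, inverse = TRUE) / n)
}

# exhaustive rank-sum reference: two-sided p from the permutation
# distribution of the group-A rank sum over all assignments
exact_ranksum_p <- function(a, b) {
  na <- length(a); N <- na + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  combos <- utils::combn(N, na)
  w_all <- colSums(matrix(r[combos], nrow = na))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# direct binomial upper-tail by term-wise summation
enum_binom_tail <- function(n, p, k) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# small fast cohort spec used across pipeline tests
tiny_cohort_spec <- function(..., seed = 1) {
  cohort_spec(n_patient = 5L, n_control = 5L, duration = 600,
              fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100, fs_resp = 50,
              n_fnirs = 4L, n_eeg = 3L, seed = seed, ...)
}

# fast analysis settings matched to tiny cohorts
fast_config <- function(...) {
  analysis_config(voices = 6L, fmax_fnirs = 1.8, fs_analysis = 4, ...)
}
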