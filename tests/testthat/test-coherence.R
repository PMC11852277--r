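test_that("phase coherence is 1 for identical signals and lives in [0,1]", {
  set.seed(21)
  fs <- 4
  x <- time_series(phase_randomized_noise(2400, fs, 21), fs)
  wt <- morlet_wt(x, 0.02, 1.8, voices = 12)
  cs <- wpc(wt, wt)
  ok <- !is.na(cs$wpc)
  expect_true(all(abs(cs$wpc[ok] - 1) < 1e-9))
  expect_true(all(cs$wpc[ok] >= 0 & cs$wpc[ok] <= 1 + 1e-12))
})

test_that("delayed copies give near-unit coherence and the shift-law phase", {
  fs <- 20; tau <- 2.5
  t <- seq(0, 2000 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.2 * t)
  y <- c(numeric(tau * fs), x[1:(length(x) - tau * fs)])
  cs <- wpc(morlet_wt(time_series(x, fs), 0.05, 1),
            morlet_wt(time_series(y, fs), 0.05, 1))
  k <- which.min(abs(cs$grid$freqs - 0.2))
  expect_gt(cs$wpc[k], 0.99)
  # 2 pi f tau = pi at 0.2 Hz: the wrap point, so compare magnitudes
  expect_lt(abs(abs(cs$phase_mean[k]) - pi), 0.05)
  expect_equal(abs(estimate_time_lag(cs, 0.2)), 2.5, tolerance = 0.05)
})

test_that("independent noises give low coherence that falls with length", {
  fs <- 4
  cs <- wpc(morlet_wt(time_series(phase_randomized_noise(6000, fs, 1), fs),
                      0.02, 1.8, voices = 12),
            morlet_wt(time_series(phase_randomized_noise(6000, fs, 2), fs),
                      0.02, 1.8, voices = 12))
  k <- which.min(abs(cs$grid$freqs - 0.1))
  expect_lt(cs$wpc[k], 0.3)

  med_wpc <- function(n, seed_base) {
    v <- vapply(1:6, function(i) {
      a <- morlet_wt(time_series(
        phase_randomized_noise(n, fs, seed_base + 2 * i), fs),
        0.05, 1.8, voices = 12)
      b <- morlet_wt(time_series(
        phase_randomized_noise(n, fs, seed_base + 2 * i + 1), fs),
        0.05, 1.8, voices = 12)
      stats::median(wpc(a, b)$wpc, na.rm = TRUE)
    }, numeric(1))
    stats::median(v)
  }
  expect_lt(med_wpc(8000, 100), med_wpc(2000, 200))
})

test_that("coherence is symmetric, amplitude-blind and convention-flagged", {
  set.seed(31)
  fs <- 4; n <- 2400
  t <- (0:(n - 1)) / fs
  shared <- cumsum(rnorm(n)) * 0.02
  x <- time_series(sin(2 * pi * 0.1 * t + shared) + 0.3 * rnorm(n), fs)
  y <- time_series(sin(2 * pi * 0.1 * t + shared + 1) + 0.3 * rnorm(n), fs)
  wx <- morlet_wt(x, 0.02, 1.8, voices = 12)
  wy <- morlet_wt(y, 0.02, 1.8, voices = 12)
  cxy <- wpc(wx, wy); cyx <- wpc(wy, wx)
  expect_equal(cxy$wpc, cyx$wpc, tolerance = 1e-12)
  ok <- !is.na(cxy$phase_mean) & cxy$wpc > 0.05
  wrap <- function(a) atan2(sin(a), cos(a))
  expect_lt(max(abs(wrap(cxy$phase_mean[ok] + cyx$phase_mean[ok]))), 1e-6)

  # scaling either input leaves coherence untouched
  x50 <- time_series(50 * x$samples, fs)
  c_scaled <- wpc(morlet_wt(x50, 0.02, 1.8, voices = 12), wy)
  expect_lt(max(abs(c_scaled$wpc - cxy$wpc), na.rm = TRUE), 1e-10)

  # slow amplitude modulation leaves the analytic phase nearly intact
  am <- time_series((1 + 0.5 * sin(2 * pi * 0.003 * t)) * x$samples, fs)
  c_am <- wpc(morlet_wt(am, 0.02, 1.8, voices = 12), wy)
  k <- which.min(abs(cxy$grid$freqs - 0.1))
  expect_lt(abs(c_am$wpc[k] - cxy$wpc[k]), 1e-2)

  csq <- wpc(wx, wy, convention = "squared")
  expect_equal(csq$wpc, cxy$wpc^2, tolerance = 1e-12)
})

test_that("surrogate thresholds behave on shared and independent cohorts", {
  fs <- 4; n <- 1200
  mk_wt <- function(x) morlet_wt(time_series(x, fs), 0.05, 1.8,
                                 voices = 10)
  # subjects share channel a exactly; channel b independent: genuine
  # coherence is itself a draw from the surrogate distribution
  set.seed(51)
  shared_a <- phase_randomized_noise(n, fs, 500)
  N <- 10
  wts_a <- lapply(1:N, function(i) mk_wt(shared_a))
  wts_b <- lapply(1:N, function(i)
    mk_wt(phase_randomized_noise(n, fs, 600 + i)))
  effs <- vapply(1:N, function(i) {
    st <- inter_subject_threshold(wts_a, wts_b, i)
    cs <- wpc(wts_a[[i]], wts_b[[i]])
    stats::median(effective_coherence(cs, st)$effective, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(stats::median(effs)), 0.08)

  expect_error(inter_subject_threshold(wts_a[1:2], wts_b[1:2], 1),
               "at least 8")
})

test_that("effective coherence is plain subtraction without clipping", {
  fs <- 4
  wt <- morlet_wt(time_series(phase_randomized_noise(1200, fs, 3), fs),
                  0.05, 1.8, voices = 10)
  cs <- wpc(wt, wt)
  st <- structure(list(thresh = cs$wpc, prob = 0.95, n_surrogates = 10,
                       scheme = "test", grid = cs$grid),
                  class = "surrogate_threshold")
  eff <- effective_coherence(cs, st)
  expect_equal(max(abs(eff$effective), na.rm = TRUE), 0, tolerance = 1e-12)

  st2 <- st; st2$thresh <- cs$wpc + 0.2
  eff2 <- effective_coherence(cs, st2)
  expect_true(all(eff2$effective < 0, na.rm = TRUE))
})

test_that("montage pair enumeration and global averages are complete", {
  probes <- paste0("N", 1:11)
  pr <- channel_pairs(probes)
  expect_equal(nrow(pr), 55L)
  expect_equal(nrow(cross_pairs(paste0("E", 1:16), probes)), 176L)

  vals <- stats::setNames(rep(0.42, 55), pr$pair)
  expect_equal(global_coherence(vals, probes), 0.42)

  # flipped orientation is accepted; missing pairs are named
  names(vals)[1] <- "N2~N1"
  expect_equal(global_coherence(vals, probes), 0.42)
  expect_error(global_coherence(vals[-2], probes), pr$pair[2])
})

test_that("phase differences convert to time lags with the sign convention", {
  expect_equal(estimate_time_lag(-pi, 0.2), -2.5)
  expect_equal(estimate_time_lag(0, 0.7), 0)

  # known 1 s delay recovered across 0.1-0.3 Hz from broadband signals
  fs <- 20; tau <- 1
  set.seed(61)
  x <- phase_randomized_noise(40000, fs, 61)
  y <- c(numeric(tau * fs), x[1:(40000 - tau * fs)])
  cs <- wpc(morlet_wt(time_series(x, fs), 0.05, 1),
            morlet_wt(time_series(y, fs), 0.05, 1))
  for (f in c(0.1, 0.2, 0.3))
    expect_lt(abs(estimate_time_lag(cs, f) - 1), 0.1)
})
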