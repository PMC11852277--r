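test_that("peak detection recovers pulse trains and rejects flat channels", {
  peaks <- seq(0.5, 299.5, by = 1)
  ev <- detect_peaks(pulse_train_ts(peaks, 100, 300, noise = 0.05), "ecg")
  expect_length(ev$peak_times, length(peaks))
  expect_lt(max(abs(ev$peak_times - peaks)), 0.010)

  # one maximum per cycle of a slow sinusoid
  evs <- detect_peaks(sine_ts(0.25, 100, 300), "respiration")
  expect_true(abs(length(evs$peak_times) - 75) <= 1)

  expect_error(detect_peaks(time_series(rep(1, 30000), 100), "ecg"),
               "unusable")
})

test_that("rate series follow the midpoint/inverse-interval definition", {
  r <- build_rate(0:10, fs_out = 100)
  expect_equal(range(r$samples), c(1, 1), tolerance = 1e-9)

  # anchors (0.5 s, 1 Hz) and (1.25 s, 2 Hz); linear between
  r2 <- build_rate(c(0, 1, 1.5), fs_out = 100)
  expect_equal(r2$t0, 0.5)
  v <- approx(ts_times(r2), r2$samples, xout = 0.875)$y
  expect_equal(v, 1.5, tolerance = 1e-6)

  expect_error(build_rate(c(0, 1, 0.5)), "strictly increasing")
  expect_error(build_rate(c(0, 1)), "at least 3")
})

test_that("rate series recover a modulated heart rhythm", {
  # beat times from integrating f(t) = 1.1 + 0.1 sin(2 pi 0.25 t)
  fs_i <- 1000
  tt <- seq(0, 300, by = 1 / fs_i)
  phi <- 2 * pi * cumsum(1.1 + 0.1 * sin(2 * pi * 0.25 * tt)) / fs_i
  beats <- approx(phi, tt, xout = 2 * pi * seq_len(floor(max(phi) /
                                                           (2 * pi))))$y
  r <- build_rate(beats)
  expect_equal(r$fs, 20)
  expect_lt(abs(mean(r$samples) - 1.1) / 1.1, 0.01)
  # modulation frequency appears as the spectral peak of the rate series
  wt <- morlet_wt(r, 0.05, 1)
  expect_equal(wt$grid$freqs[which.max(time_avg_power(wt)$power)], 0.25,
               tolerance = 0.02)
})

test_that("rate construction is offset-invariant and scales with intervals", {
  set.seed(9)
  beats <- cumsum(runif(80, 0.8, 1.2))
  r0 <- build_rate(beats, fs_out = 100)
  r_off <- build_rate(beats + 500, fs_out = 100)
  expect_equal(r0$samples, r_off$samples, tolerance = 1e-9)
  expect_equal(r_off$t0 - r0$t0, 500, tolerance = 1e-9)

  r_half <- build_rate(beats * 2, fs_out = 100)
  idx <- seq(1, length(r_half$samples), by = 2)[seq_along(r0$samples)]
  expect_equal(r_half$samples[idx], r0$samples / 2, tolerance = 1e-6)
})

test_that("rate series are band-limited below half the event rate", {
  # smoothly modulated ~1 Hz beat train, as a physiological heart produces
  fs_i <- 1000
  tt <- seq(0, 300, by = 1 / fs_i)
  fmod <- 1.0 + 0.08 * sin(2 * pi * 0.1 * tt) + 0.03 * sin(2 * pi * 0.25 * tt)
  phi <- 2 * pi * cumsum(fmod) / fs_i
  beats <- approx(phi, tt, xout = 2 * pi * seq_len(floor(max(phi) /
                                                           (2 * pi))))$y
  r <- build_rate(beats)
  x <- r$samples - mean(r$samples)
  pg <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * r$fs
  half <- f <= r$fs / 2
  hi <- half & f > 0.5                         # above half the mean rate
  expect_lt(sum(pg[hi]) / sum(pg[half & f > 0]), 0.05)
})

test_that("summaries and ridge cross-checks behave", {
  r_const <- build_rate(0:20, fs_out = 100)
  expect_equal(rate_summary(r_const), list(mean = 1, sd = 0),
               tolerance = 1e-9)

  # clean synthetic ECG agrees with its own wavelet ridge
  fs_i <- 1000
  tt <- seq(0, 400, by = 1 / fs_i)
  phi <- 2 * pi * cumsum(1.0 + 0.05 * sin(2 * pi * 0.08 * tt)) / fs_i
  beats <- approx(phi, tt, xout = 2 * pi * seq_len(floor(max(phi) /
                                                           (2 * pi))))$y
  ecg <- pulse_train_ts(beats, 100, 400, noise = 0.05)
  rate <- build_rate(detect_peaks(ecg, "ecg"))
  wt <- morlet_wt(ecg, 0.6, 2, f0 = 2, voices = 48)
  rg <- extract_ridge(wt, c(0.6, 2))
  chk <- crosscheck_rate_with_ridge(rate, rg)
  expect_lt(chk$median_abs_diff, 0.02)
  expect_false(chk$flag)

  # missed beats degrade agreement monotonically; the median statistic is
  # robust to sporadic misses, so the flag fires only on wholesale
  # misestimation such as a halved rate (every other beat missed)
  set.seed(2)
  mads <- vapply(c(0.1, 0.2), function(frac) {
    keep <- sort(sample(seq_along(beats),
                        round((1 - frac) * length(beats))))
    crosscheck_rate_with_ridge(build_rate(beats[keep]), rg)$median_abs_diff
  }, numeric(1))
  expect_true(all(mads > chk$median_abs_diff))
  expect_true(all(diff(c(chk$median_abs_diff, mads)) > 0))
  halved <- build_rate(beats[seq(1, length(beats), by = 2)])
  chk_bad <- crosscheck_rate_with_ridge(halved, rg)
  expect_true(chk_bad$flag)

  # a ridge that equals the rate itself gives zero difference
  fake <- structure(list(freq_track = rate$samples,
                         amp_track = rep(1, length(rate$samples)),
                         index_track = rep(1L, length(rate$samples)),
                         band = c(0.6, 2), fs = rate$fs, t0 = rate$t0,
                         label = ""), class = "ridge")
  expect_equal(crosscheck_rate_with_ridge(rate, fake)$median_abs_diff, 0,
               tolerance = 1e-9)
})
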