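test_that("frequency grid is logarithmic with constant ratio", {
  g <- freq_grid(0.005, 4, 32)
  expect_true(all(diff(g$freqs) > 0))
  ratios <- g$freqs[-1] / g$freqs[-length(g$freqs)]
  expect_lt(diff(range(ratios)), 1e-12)
  expect_equal(ratios[1], 2^(1 / 32), tolerance = 1e-12)
  expect_error(freq_grid(0.1, 0.05), "fmin < fmax")
})

test_that("wavelet transform localizes sinusoids on the grid", {
  fs <- 20
  wt <- morlet_wt(sine_ts(0.1, fs, 2000), 0.005, 2)
  ps <- time_avg_power(wt)
  k_hat <- which.max(ps$power)
  expect_equal(k_hat, which.min(abs(wt$grid$freqs - 0.1)))

  # zero signal: exactly zero coefficients
  wt0 <- morlet_wt(time_series(numeric(40000), fs), 0.005, 2)
  expect_equal(max(Mod(wt0$coeffs)), 0)

  # two tones resolve into two local maxima, cross-checked against a
  # Fourier periodogram oracle
  t <- seq(0, 2000 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 0.03 * t) + sin(2 * pi * 0.3 * t)
  wt2 <- morlet_wt(time_series(x, fs), 0.005, 2)
  a <- time_avg_power(wt2)$power
  loc_max <- which(diff(sign(diff(a))) < 0) + 1L
  loc_max <- loc_max[a[loc_max] > 0.05 * max(a, na.rm = TRUE)]
  expect_length(loc_max, 2L)
  expect_equal(sort(loc_max),
               sort(c(which.min(abs(wt2$grid$freqs - 0.03)),
                      which.min(abs(wt2$grid$freqs - 0.3)))))
  pg <- Mod(fft(x))[1:20000]
  f_pg <- (0:19999) / length(x) * fs
  top2 <- sort(f_pg[order(pg, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(0.03, 0.3), tolerance = 0.01)

  expect_error(morlet_wt(sine_ts(0.5, 20, 30), fmin = 0.005),
               "fmin = 0.005")
})

test_that("transform is linear and time-shift covariant", {
  fs <- 10
  set.seed(7)
  n <- 3000
  x <- rnorm(n); y <- rnorm(n)
  wt_mix <- morlet_wt(time_series(2 * x - 3 * y, fs), 0.05, 2)
  wt_x <- morlet_wt(time_series(x, fs), 0.05, 2)
  wt_y <- morlet_wt(time_series(y, fs), 0.05, 2)
  expect_lt(max(Mod(wt_mix$coeffs - (2 * wt_x$coeffs - 3 * wt_y$coeffs))),
            1e-9 * max(Mod(wt_mix$coeffs)))

  # shifting the input shifts the coefficients (interior region)
  d <- 200L
  xs <- c(x[(d + 1):n], x[1:d])          # circular shift for exactness
  wt_s <- morlet_wt(time_series(xs, fs), 0.05, 2)
  interior <- 1000:1800
  expect_lt(max(Mod(wt_s$coeffs[, interior - d] -
                      wt_x$coeffs[, interior])),
            0.02 * max(Mod(wt_x$coeffs)))
})

test_that("grid frequencies are recovered and f0 sharpens the response", {
  fs <- 10
  g <- freq_grid(0.01, 2, 16)
  for (f in g$freqs[c(20, 60, 100)]) {
    wt <- morlet_wt(sine_ts(f, fs, max(600, 4 / 0.01)), 0.01, 2,
                    voices = 16)
    expect_equal(which.max(time_avg_power(wt)$power),
                 which.min(abs(g$freqs - f)))
  }
  # doubling f0 narrows the frequency response: less amplitude off-peak
  ts <- sine_ts(0.2, fs, 1500)
  off <- function(f0) {
    wt <- morlet_wt(ts, 0.05, 1, f0 = f0)
    a <- time_avg_power(wt)$power
    a[which.min(abs(wt$grid$freqs - 0.3))]
  }
  expect_lt(off(2), off(1))
  expect_lt(off(4), off(2))
})

test_that("time-averaged power follows the amplitude convention", {
  fs <- 20
  p1 <- time_avg_power(morlet_wt(sine_ts(0.2, fs, 1000, amp = 1),
                                 0.05, 2))
  p2 <- time_avg_power(morlet_wt(sine_ts(0.2, fs, 1000, amp = 2),
                                 0.05, 2))
  k <- which.max(p1$power)
  expect_equal(p2$power[k] / p1$power[k], 4, tolerance = 0.02)

  expect_equal(max(time_avg_power(
    morlet_wt(time_series(numeric(20000), fs), 0.05, 2))$power), 0)

  # amplitude modulation separates the two conventions (Jensen)
  t <- seq(0, 1000 - 1 / fs, by = 1 / fs)
  am <- (1 + 0.8 * sin(2 * pi * 0.01 * t)) * sin(2 * pi * 0.2 * t)
  wt <- morlet_wt(time_series(am, fs), 0.05, 2)
  k2 <- which.min(abs(wt$grid$freqs - 0.2))
  p_amp <- time_avg_power(wt)$power[k2]
  p_en <- time_avg_power(wt, convention = "energy")$power[k2]
  expect_lt(p_amp, p_en)
})

test_that("instantaneous phase obeys quadrature, negation and delay laws", {
  fs <- 20; dur <- 2000
  wt_sin <- morlet_wt(sine_ts(0.1, fs, dur), 0.005, 2)
  wt_cos <- morlet_wt(sine_ts(0.1, fs, dur, phase = pi / 2), 0.005, 2)
  k <- which.min(abs(wt_sin$grid$freqs - 0.1))
  mid <- 20000:24000
  dphi <- Arg(wt_sin$coeffs[k, mid] * Conj(wt_cos$coeffs[k, mid]))
  expect_lt(max(abs(dphi + pi / 2)), 0.05)

  wt_neg <- morlet_wt(sine_ts(0.1, fs, dur, amp = -1), 0.005, 2)
  dneg <- Arg(wt_sin$coeffs[k, mid] * Conj(wt_neg$coeffs[k, mid]))
  expect_lt(max(abs(abs(dneg) - pi)), 0.05)

  # delay tau at frequency f shifts phase by 2 pi f tau
  tau <- 1.25; f <- 0.2
  wt_a <- morlet_wt(sine_ts(f, fs, dur), 0.05, 2)
  wt_b <- morlet_wt(sine_ts(f, fs, dur, phase = -2 * pi * f * tau),
                    0.05, 2)
  k2 <- which.min(abs(wt_a$grid$freqs - f))
  dd <- Arg(wt_a$coeffs[k2, mid] * Conj(wt_b$coeffs[k2, mid]))
  expect_lt(max(abs(dd - 2 * pi * f * tau)), 0.05)

  ph <- instantaneous_phase(wt_sin)
  expect_true(all(ph$phase > -pi & ph$phase <= pi, na.rm = TRUE))
})

test_that("ridge extraction tracks stationary tones, chirps and wobble", {
  fs <- 20
  tt <- seq(0, 600 - 1 / fs, by = 1 / fs)

  wt_st <- morlet_wt(sine_ts(1, fs, 600), 0.4, 3)
  rg_st <- extract_ridge(wt_st, c(0.6, 2))
  k_near <- wt_st$grid$freqs[which.min(abs(wt_st$grid$freqs - 1))]
  mid <- 2000:10000
  expect_true(all(rg_st$freq_track[mid] == k_near))

  finst <- 0.8 + 0.4 * tt / 600
  wt_ch <- morlet_wt(time_series(sin(2 * pi * cumsum(finst) / fs), fs),
                     0.4, 3)
  rg_ch <- extract_ridge(wt_ch, c(0.6, 2))
  err_steps <- abs(log2(rg_ch$freq_track[mid] / finst[mid])) * 32
  expect_lt(max(err_steps), 2)

  # IHR-like wobble: mean instantaneous frequency recovered
  fw <- 1.1 + 0.1 * sin(2 * pi * 0.25 * tt)
  wt_w <- morlet_wt(time_series(sin(2 * pi * cumsum(fw) / fs), fs),
                    0.4, 3, f0 = 2)
  rg_w <- extract_ridge(wt_w, c(0.6, 2))
  expect_lt(abs(mean(rg_w$freq_track[mid]) - 1.1), 0.02)

  expect_error(extract_ridge(wt_st, c(3, 4)), "no grid frequency")
})

test_that("band averaging is the half-open arithmetic mean on the grid", {
  g <- freq_grid(0.005, 2, 16)
  expect_equal(band_average(rep(3.3, length(g$freqs)), c(0.05, 0.15),
                            freqs = g$freqs), 3.3)

  fb <- frequency_bands()
  myo <- fb[fb$band == "myogenic", ]
  ind <- as.numeric(g$freqs >= myo$fmin & g$freqs < myo$fmax)
  expect_equal(band_average(ind, "myogenic", freqs = g$freqs), 1)
  expect_equal(band_average(ind, "cardiac", freqs = g$freqs), 0)

  # linear-in-log-frequency curve vs direct summation oracle
  curve <- 2 + 0.5 * log(g$freqs)
  sel <- g$freqs >= 0.021 & g$freqs < 0.052
  expect_equal(band_average(curve, "neurogenic", freqs = g$freqs),
               sum(curve[sel]) / sum(sel))

  expect_error(band_average(curve, c(5, 6), freqs = g$freqs),
               "no grid frequency")
})
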