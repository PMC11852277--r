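test_that("cohort generation is deterministic and correctly sized", {
  spec <- cohort_spec(n_patient = 19, n_control = 20, duration = 60,
                      fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100,
                      fs_resp = 50, n_fnirs = 3, n_eeg = 2, seed = 77)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_length(co1$subjects, 39L)
  expect_equal(sum(co1$manifest$group == "patient"), 19L)
  expect_identical(co1$subjects[[5]]$fnirs$N2$samples,
                   co2$subjects[[5]]$fnirs$N2$samples)
  expect_identical(co1$ledger, co2$ledger)

  # ledger respiration rates concentrate at the group targets
  med <- tapply(co1$ledger$resp_rate, co1$ledger$group, stats::median)
  expect_lt(abs(med[["control"]] - 0.21), 0.02)
  expect_lt(abs(med[["patient"]] - 0.28), 0.02)

  expect_error(cohort_spec(fs_fnirs = 2), "aliases")
})

test_that("zero jitter gives unit coherence; zero coupling decouples EEG", {
  nb <- band_oscillators()
  nb$jitter_control[] <- 0
  spec <- cohort_spec(n_patient = 1, n_control = 1, duration = 600,
                      fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100,
                      fs_resp = 50, n_fnirs = 2, n_eeg = 1,
                      noise_fnirs = 0, bands = nb, seed = 5)
  s <- generate_subject(spec, "control", seed = 9)
  w1 <- morlet_wt(s$fnirs$N1, 0.02, 1.8, voices = 10)
  w2 <- morlet_wt(s$fnirs$N2, 0.02, 1.8, voices = 10)
  cs <- wpc(w1, w2)
  bands <- frequency_bands()
  for (bd in c("neurogenic", "myogenic", "respiration"))
    expect_gt(band_average(cs, bd), 0.97)

  # rho = 0: EEG carries no band rhythm, fNIRS~EEG coherence stays low
  nb2 <- band_oscillators()
  nb2$rho_control[] <- 0
  spec2 <- cohort_spec(n_patient = 1, n_control = 1, duration = 600,
                       fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100,
                       fs_resp = 50, n_fnirs = 1, n_eeg = 1,
                       cardiac_crosstalk_eeg = 0, bands = nb2, seed = 6)
  s2 <- generate_subject(spec2, "control", seed = 10)
  cs2 <- wpc(morlet_wt(s2$fnirs$N1, 0.02, 1.8, voices = 10),
             morlet_wt(s2$eeg$Fp1, 0.02, 1.8, voices = 10))
  expect_lt(band_average(cs2, "myogenic"), 0.45)
  expect_lt(band_average(cs2, "neurogenic"), 0.45)
})

test_that("cardio estimates recover ledger truth on clean settings", {
  spec <- cohort_spec(n_patient = 1, n_control = 1, duration = 300,
                      fs_fnirs = 10, fs_eeg = 10, fs_ecg = 200,
                      fs_resp = 100, n_fnirs = 1, n_eeg = 1,
                      noise_ecg = 0, noise_resp = 0, seed = 3)
  s <- generate_subject(spec, "control", seed = 33)
  ihr <- build_rate(detect_peaks(resample_ts(s$ecg, 100), "ecg"))
  expect_lt(abs(rate_summary(ihr)$mean - s$truth$heart_rate_mean_true) /
              s$truth$heart_rate_mean_true, 0.02)
  irr <- build_rate(detect_peaks(s$resp, "respiration"))
  expect_lt(abs(rate_summary(irr)$mean - s$truth$resp_rate_mean_true) /
              s$truth$resp_rate_mean_true, 0.02)
})

test_that("band power grows with generated amplitude", {
  amps <- c(0.25, 0.5, 1, 2, 4)
  for (seed in c(14, 15, 16)) {
    pw <- vapply(amps, function(a) {
      nb <- band_oscillators()
      nb$amp_control[nb$band == "myogenic"] <- a
      spec <- cohort_spec(n_patient = 1, n_control = 1, duration = 600,
                          fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100,
                          fs_resp = 50, n_fnirs = 1, n_eeg = 1,
                          bands = nb, seed = 1)
      s <- generate_subject(spec, "control", seed = seed)
      band_average(time_avg_power(morlet_wt(s$fnirs$N1, 0.02, 1.8,
                                            voices = 10)), "myogenic")
    }, numeric(1))
    expect_true(all(diff(pw) > 0))
  }
})

test_that("inter-channel coherence decreases with jitter", {
  jits <- c(0.05, 0.15, 0.3, 0.5, 0.8, 1.2, 1.8, 2.5)
  co <- vapply(jits, function(j) {
    nb <- band_oscillators()
    nb$jitter_control[] <- j
    spec <- cohort_spec(n_patient = 1, n_control = 1, duration = 600,
                        fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100,
                        fs_resp = 50, n_fnirs = 2, n_eeg = 1,
                        bands = nb, seed = 2)
    s <- generate_subject(spec, "control", seed = 44)
    cs <- wpc(morlet_wt(s$fnirs$N1, 0.05, 1.8, voices = 10),
              morlet_wt(s$fnirs$N2, 0.05, 1.8, voices = 10))
    band_average(cs, "myogenic")
  }, numeric(1))
  expect_lt(cor(jits, co, method = "spearman"), -0.95)
})

test_that("respiratory sinus arrhythmia couples IHR to respiration", {
  spec <- cohort_spec(n_patient = 1, n_control = 9, duration = 600,
                      fs_fnirs = 10, fs_eeg = 10, fs_ecg = 100,
                      fs_resp = 50, n_fnirs = 1, n_eeg = 1,
                      rsa_strength = 0.05, seed = 12)
  co <- generate_cohort(spec)
  wts_ihr <- list(); wts_resp <- list()
  for (s in co$subjects) {
    ihr <- build_rate(detect_peaks(s$ecg, "ecg"))
    resp <- resample_ts(s$resp, 20)
    al <- nvosc:::.align_pair(bandpass_zerophase(detrend_poly(ihr),
                                                 0.02, 2), resp)
    wts_ihr[[s$id]] <- morlet_wt(al[[1]], 0.05, 1, voices = 10)
    wts_resp[[s$id]] <- morlet_wt(al[[2]], 0.05, 1, voices = 10)
  }
  i <- 1
  cs <- wpc(wts_ihr[[i]], wts_resp[[i]])
  st <- inter_subject_threshold(wts_ihr, wts_resp, i)
  f_resp <- co$ledger$resp_rate[i]
  k <- which.min(abs(cs$grid$freqs - f_resp))
  expect_gt(cs$wpc[k], st$thresh[k])
})
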