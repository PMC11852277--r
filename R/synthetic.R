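#' Default band-oscillator specifications for the synthetic cohort
#'
#' One oscillator per cardiovascular frequency band, centred at the band's
#' geometric-mean frequency. The respiration and cardiac rows take their
#' phase from the generated respiration and heart rhythms rather than an
#' autonomous oscillator. Per-group columns encode the built-in group
#' contrasts: patients have reduced neurogenic/myogenic (and mildly
#' endothelial) amplitudes, and larger channel phase jitter in every band,
#' which lowers inter-channel phase coherence across the board. `rho` is
#' the neurovascular coupling weight with which each band's rhythm enters
#' the EEG channels.
#'
#' @return `data.frame` with columns `band`, `source`, `f_centre` (Hz; NA
#'   for rhythm-driven rows), `amp_control`, `amp_patient`, `wander_frac`,
#'   `wander_tau` (s), `jitter_control`, `jitter_patient` (rad),
#'   `rho_control`, `rho_patient`.
#' @export
band_oscillators <- function() {
  fb <- frequency_bands()
  data.frame(
    band = fb$band,
    source = c("autonomous", "autonomous", "autonomous", "autonomous",
               "respiration", "cardiac"),
    f_centre = c(sqrt(fb$fmin[1:4] * fb$fmax[1:4]), NA, NA),
    amp_control = c(1, 1, 1, 1, 1, 1),
    amp_patient = c(0.8, 1, 0.6, 0.6, 1, 1),
    wander_frac = c(0.1, 0.1, 0.1, 0.1, 0.05, 0),
    wander_tau = c(100, 100, 100, 100, 60, NA),
    jitter_control = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    jitter_patient = c(1.1, 1.1, 1.1, 1.1, 1.1, 1.1),
    rho_control = c(0.2, 0.2, 0.4, 0.5, 0.3, 0.3),
    rho_patient = c(0.2, 0.2, 0.1, 0.1, 0.3, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults match the study conditions the generator emulates: 19 patients
#' and 20 controls, 25-minute records, fNIRS/EEG at 31.25 Hz, ECG and
#' respiration effort at 1200 Hz, respiration rates around 0.21 Hz
#' (control) versus 0.28 Hz (patient), heart rate around 1 Hz with
#' respiratory sinus arrhythmia.
#'
#' @param n_patient,n_control Group sizes.
#' @param duration Record length in seconds.
#' @param fs_fnirs,fs_eeg,fs_ecg,fs_resp Per-modality sampling rates, Hz.
#' @param n_fnirs,n_eeg Montage sizes (11 fNIRS probes, 16 EEG channels).
#' @param resp_rate_control,resp_rate_patient Group mean respiration
#'   rates, Hz.
#' @param resp_rate_sd Between-subject SD of the respiration rate, Hz.
#' @param heart_rate_mean,heart_rate_sd Heart-rate distribution, Hz (no
#'   group contrast by default).
#' @param rsa_strength Respiratory-sinus-arrhythmia modulation depth of
#'   the heart rate, Hz.
#' @param noise_fnirs,noise_eeg,noise_ecg,noise_resp Measurement-noise
#'   scales per modality (EEG noise is 1/f-shaped, others white).
#' @param cardiac_crosstalk_eeg Amplitude of the cardiac electrical
#'   cross-talk added to every EEG channel.
#' @param ecg_pulse_width Gaussian R-wave width (SD), seconds.
#' @param jitter_tau Timescale (s) of the slowly wandering per-channel
#'   phase offsets whose SD is each band's jitter parameter.
#' @param band_amp_sd Between-subject lognormal SD of each band's
#'   amplitude (physiological heterogeneity; mean-1, per subject and
#'   band).
#' @param channel_gain_sd Per-channel lognormal gain SD (sensor/optode
#'   coupling variability; mean-1, per channel).
#' @param bands Band-oscillator table, see [band_oscillators()].
#' @param seed Master seed; per-subject seeds derive from it.
#' @return Object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_patient = 19L, n_control = 20L, duration = 1500,
                        fs_fnirs = 31.25, fs_eeg = 31.25, fs_ecg = 1200,
                        fs_resp = 1200, n_fnirs = 11L, n_eeg = 16L,
                        resp_rate_control = 0.21, resp_rate_patient = 0.28,
                        resp_rate_sd = 0.02, heart_rate_mean = 1.0,
                        heart_rate_sd = 0.08, rsa_strength = 0.05,
                        noise_fnirs = 0.1, noise_eeg = 0.5,
                        noise_ecg = 0.05, noise_resp = 0.05,
                        cardiac_crosstalk_eeg = 0.3,
                        ecg_pulse_width = 0.02, jitter_tau = 30,
                        band_amp_sd = 0.2, channel_gain_sd = 0.2,
                        bands = band_oscillators(), seed = 1L) {
  spec <- as.list(environment())
  f_max <- max(heart_rate_mean + 4 * heart_rate_sd + rsa_strength,
               max(bands$f_centre, na.rm = TRUE) *
                 (1 + max(bands$wander_frac)))
  for (fs_name in c("fs_fnirs", "fs_eeg", "fs_ecg", "fs_resp"))
    if (spec[[fs_name]] <= 2 * f_max)
      stop(sprintf("%s = %g Hz aliases generated content (max ~%.2f Hz)",
                   fs_name, spec[[fs_name]], f_max), call. = FALSE)
  if (n_patient < 1L || n_control < 1L || duration <= 0)
    stop("invalid cohort dimensions", call. = FALSE)
  structure(spec, class = "cohort_spec")
}

# smooth unit-variance wander process: cubic-spline interpolation through
# i.i.d. standard-normal knots spaced `tau` seconds apart. Returns a
# function of time so the same realization can be evaluated on any
# modality's sampling grid.
.wander_fn <- function(duration, tau) {
  kt <- seq(-tau, duration + tau, by = tau)
  kv <- stats::rnorm(length(kt))
  fn <- stats::splinefun(kt, kv, method = "natural")
  function(t) fn(t)
}

# integrate an instantaneous-frequency function onto a sampling grid
.phase_from_freq <- function(f_vals, fs) {
  2 * pi * cumsum(f_vals) / fs
}

# 1/f-shaped noise via spectral shaping, unit RMS before scaling
.pink_noise <- function(n, fs) {
  nfft <- stats::nextn(n, 2)
  xf <- stats::fft(stats::rnorm(nfft))
  f <- (seq_len(nfft) - 1L) / nfft * fs
  f[f > fs / 2] <- fs - f[f > fs / 2]
  w <- ifelse(f > 0, 1 / sqrt(pmax(f, fs / nfft)), 0)
  y <- Re(stats::fft(xf * w, inverse = TRUE) / nfft)[seq_len(n)]
  y / stats::sd(y)
}

.eeg_montage <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
                  "T3", "T4", "T5", "T6", "P3", "P4", "O1", "O2")

#' Generate one synthetic subject recording
#'
#' Simulates a multichannel resting-state recording: per band a
#' subject-level phase integrated from a slowly wandering instantaneous
#' frequency; fNIRS channels as jittered-phase copies of every band's
#' rhythm plus white noise; EEG channels as 1/f noise plus
#' neurovascular-coupled band rhythms and cardiac cross-talk; an ECG-like
#' Gaussian R-wave train whose instantaneous rate carries respiratory
#' sinus arrhythmia; and a sinusoidal respiration-effort trace at the
#' subject's respiration rate. All ground-truth parameters are returned in
#' `$truth`.
#'
#' @param spec A [cohort_spec()].
#' @param group `"patient"` or `"control"`.
#' @param seed Subject seed (integer).
#' @param id Subject identifier string.
#' @return Object of class `subject_recording`: list with `id`, `group`,
#'   `fnirs` (named list of [time_series]), `eeg`, `ecg`, `resp`, `truth`.
#' @export
generate_subject <- function(spec, group = c("control", "patient"),
                             seed = 1L, id = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  set.seed(seed)
  dur <- spec$duration
  g <- function(col) spec$bands[[paste0(col, "_", group)]]
  amp <- g("amp"); jit <- g("jitter"); rho <- g("rho")
  nb <- nrow(spec$bands)

  # subject-level rates
  resp_target <- if (group == "patient") spec$resp_rate_patient
                 else spec$resp_rate_control
  resp_rate <- max(0.08, stats::rnorm(1L, resp_target, spec$resp_rate_sd))
  heart_rate <- max(0.6, stats::rnorm(1L, spec$heart_rate_mean,
                                      spec$heart_rate_sd))
  # subject-level physiological amplitude heterogeneity (mean-1 lognormal)
  amp_subj <- amp * exp(stats::rnorm(nb, 0, spec$band_amp_sd) -
                          spec$band_amp_sd^2 / 2)

  # per-band instantaneous frequency laws (closures over shared wander
  # realizations, so every modality sees the same rhythm)
  wander <- vector("list", nb)
  for (b in seq_len(nb)) {
    tau <- spec$bands$wander_tau[b]
    wander[[b]] <- if (!is.na(tau) && spec$bands$wander_frac[b] > 0)
      .wander_fn(dur, tau) else function(t) rep(0, length(t))
  }
  freq_fn <- vector("list", nb)
  for (b in seq_len(nb)) {
    src <- spec$bands$source[b]
    fc <- switch(src, autonomous = spec$bands$f_centre[b],
                 respiration = resp_rate, cardiac = heart_rate)
    wf <- spec$bands$wander_frac[b]
    local({
      b0 <- b; fc0 <- fc; wf0 <- wf
      freq_fn[[b0]] <<- function(t) pmax(fc0 * 0.2,
                                         fc0 * (1 + wf0 * wander[[b0]](t)))
    })
  }
  i_resp <- which(spec$bands$source == "respiration")
  i_card <- which(spec$bands$source == "cardiac")

  # respiration phase on its own grid, then the RSA-modulated heart phase
  t_resp <- (seq_len(round(dur * spec$fs_resp)) - 1L) / spec$fs_resp
  phi_resp_grid <- .phase_from_freq(freq_fn[[i_resp]](t_resp), spec$fs_resp)
  phase_resp_at <- stats::approxfun(t_resp, phi_resp_grid, rule = 2)

  t_ecg <- (seq_len(round(dur * spec$fs_ecg)) - 1L) / spec$fs_ecg
  f_heart <- freq_fn[[i_card]](t_ecg) +
    spec$rsa_strength * sin(phase_resp_at(t_ecg))
  phi_heart_grid <- .phase_from_freq(f_heart, spec$fs_ecg)
  phase_heart_at <- stats::approxfun(t_ecg, phi_heart_grid, rule = 2)

  # band phases on the fNIRS/EEG grid
  t_nirs <- (seq_len(round(dur * spec$fs_fnirs)) - 1L) / spec$fs_fnirs
  phi <- matrix(0, nb, length(t_nirs))
  for (b in seq_len(nb)) {
    phi[b, ] <- switch(spec$bands$source[b],
      autonomous = .phase_from_freq(freq_fn[[b]](t_nirs), spec$fs_fnirs),
      respiration = phase_resp_at(t_nirs),
      cardiac = phase_heart_at(t_nirs))
  }

  # fNIRS: every band's rhythm with a per-channel slowly wandering phase
  # offset; the jitter SD sets how far channel phases drift apart over
  # time and thereby the inter-channel coherence level
  fnirs <- vector("list", spec$n_fnirs)
  names(fnirs) <- paste0("N", seq_len(spec$n_fnirs))
  jitter_eta <- function(b, tgrid) {
    if (jit[b] <= 0) return(rep(0, length(tgrid)))
    jit[b] * .wander_fn(dur, spec$jitter_tau)(tgrid)
  }
  gain_sd <- spec$channel_gain_sd
  for (ch in seq_len(spec$n_fnirs)) {
    x <- numeric(length(t_nirs))
    for (b in seq_len(nb))
      x <- x + amp_subj[b] * sin(phi[b, ] + jitter_eta(b, t_nirs))
    gain <- exp(stats::rnorm(1L, 0, gain_sd) - gain_sd^2 / 2)
    x <- gain * x + spec$noise_fnirs * stats::rnorm(length(x))
    fnirs[[ch]] <- time_series(x, spec$fs_fnirs, names(fnirs)[ch],
                               units = "a.u.")
  }

  # EEG: 1/f background + neurovascular-coupled rhythms + cardiac cross-talk
  t_eeg <- (seq_len(round(dur * spec$fs_eeg)) - 1L) / spec$fs_eeg
  same_grid <- isTRUE(all.equal(spec$fs_eeg, spec$fs_fnirs))
  eeg <- vector("list", spec$n_eeg)
  names(eeg) <- .eeg_montage[seq_len(spec$n_eeg)]
  for (ch in seq_len(spec$n_eeg)) {
    x <- spec$noise_eeg * .pink_noise(length(t_eeg), spec$fs_eeg)
    for (b in seq_len(nb)) {
      ph <- if (same_grid) phi[b, ] else switch(spec$bands$source[b],
        autonomous = .phase_from_freq(freq_fn[[b]](t_eeg), spec$fs_eeg),
        respiration = phase_resp_at(t_eeg),
        cardiac = phase_heart_at(t_eeg))
      x <- x + rho[b] * sin(ph + jitter_eta(b, t_eeg))
    }
    x <- x * exp(stats::rnorm(1L, 0, gain_sd) - gain_sd^2 / 2)
    x <- x + spec$cardiac_crosstalk_eeg * sin(phase_heart_at(t_eeg))
    eeg[[ch]] <- time_series(x, spec$fs_eeg, names(eeg)[ch], units = "a.u.")
  }

  # ECG: Gaussian pulses at integer crossings of the heart phase
  n_beats <- floor(phi_heart_grid[length(phi_heart_grid)] / (2 * pi))
  beat_phase <- 2 * pi * seq_len(n_beats)
  peak_times <- stats::approx(phi_heart_grid, t_ecg, xout = beat_phase)$y
  peak_times <- peak_times[!is.na(peak_times)]
  ecg_x <- spec$noise_ecg * stats::rnorm(length(t_ecg))
  w <- spec$ecg_pulse_width
  half <- ceiling(5 * w * spec$fs_ecg)
  for (pt in peak_times) {
    i0 <- max(1L, round(pt * spec$fs_ecg) - half)
    i1 <- min(length(t_ecg), round(pt * spec$fs_ecg) + half)
    idx <- i0:i1
    ecg_x[idx] <- ecg_x[idx] + exp(-(t_ecg[idx] - pt)^2 / (2 * w^2))
  }
  ecg <- time_series(ecg_x, spec$fs_ecg, "ECG", units = "a.u.")

  resp_x <- sin(phase_resp_at(t_resp)) +
    spec$noise_resp * stats::rnorm(length(t_resp))
  resp <- time_series(resp_x, spec$fs_resp, "Resp", units = "a.u.")

  truth <- list(
    group = group, seed = seed,
    resp_rate_target = resp_target, resp_rate = resp_rate,
    resp_rate_mean_true = mean(freq_fn[[i_resp]](t_resp)),
    heart_rate = heart_rate,
    heart_rate_mean_true = mean(f_heart),
    peak_times = peak_times,
    amp = stats::setNames(amp_subj, spec$bands$band),
    jitter = stats::setNames(jit, spec$bands$band),
    rho = stats::setNames(rho, spec$bands$band)
  )
  structure(list(id = id %||% sprintf("%s_%d", group, seed), group = group,
                 fnirs = fnirs, eeg = eeg, ecg = ecg, resp = resp,
                 truth = truth),
            class = "subject_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic two-group cohort
#'
#' Deterministic given the spec's master seed: per-subject seeds are drawn
#' once from the master-seeded RNG stream (`sample.int`), so subject `k`
#' always receives the same seed for a given master seed.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `cohort`: list with `subjects` (list of
#'   [generate_subject()] results), `manifest` (`data.frame` of `id`,
#'   `group`, `seed`), `ledger` (`data.frame` of per-subject ground-truth
#'   rates), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patient + spec$n_control
  groups <- c(rep("patient", spec$n_patient), rep("control", spec$n_control))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("S%02d_%s", seq_len(n), ifelse(groups == "patient",
                                                "AD", "C"))
  subjects <- vector("list", n)
  for (k in seq_len(n))
    subjects[[k]] <- generate_subject(spec, groups[k], seeds[k], ids[k])
  names(subjects) <- ids
  ledger <- do.call(rbind, lapply(subjects, function(s) data.frame(
    id = s$id, group = s$group, seed = s$truth$seed,
    resp_rate = s$truth$resp_rate,
    resp_rate_mean_true = s$truth$resp_rate_mean_true,
    heart_rate = s$truth$heart_rate,
    heart_rate_mean_true = s$truth$heart_rate_mean_true,
    n_beats = length(s$truth$peak_times),
    stringsAsFactors = FALSE)))
  rownames(ledger) <- NULL
  structure(list(subjects = subjects,
                 manifest = data.frame(id = ids, group = groups,
                                       seed = seeds,
                                       stringsAsFactors = FALSE),
                 ledger = ledger, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("<cohort> %d subjects (%d patient / %d control), ",
                     "%g s records\n"),
              length(x$subjects), sum(x$manifest$group == "patient"),
              sum(x$manifest$group == "control"), x$spec$duration))
  invisible(x)
}
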