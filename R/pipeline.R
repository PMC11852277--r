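#' Analysis configuration
#'
#' Collects every tunable of [run_analysis()] with defaults mirroring the
#' package's standard analysis: cardiovascular bands, wavelet parameters
#' per signal class, alpha 0.05, and no surrogate thresholding unless a
#' surrogate count is requested.
#'
#' @param bands Band table, see [frequency_bands()]; bands must be ordered
#'   and non-overlapping.
#' @param fmin Lower analysis frequency, Hz.
#' @param fmax_fnirs Upper analysis frequency for fNIRS/EEG, Hz (capped at
#'   0.45 fs at run time).
#' @param fmax_rate Upper analysis frequency for rate series, Hz.
#' @param f0 Wavelet frequency-resolution parameter for power/coherence
#'   analyses.
#' @param voices Grid density, voices per octave.
#' @param alpha Per-test significance level.
#' @param n_surrogates Surrogate pairings per subject and channel pair for
#'   effective coherence; 0 (default) analyses raw band coherence.
#' @param analyses Character subset of `"rates"`, `"fnirs_power"`,
#'   `"fnirs_coherence"`, `"ihr_resp_coherence"`, `"fnirs_eeg_coherence"`.
#' @param eeg_cardiac_removal Subtract the cardiac ridge mode from EEG
#'   channels before coherence analysis.
#' @param window,window_offset Analysis window (s); `NULL` window uses the
#'   whole record. The window is taken from the record start unless an
#'   offset is given.
#' @param rate_fs Sampling rate for IHR/IRR analysis series, Hz.
#' @param fs_analysis Optional analysis sampling rate (Hz) for fNIRS/EEG:
#'   channels are resampled after conditioning, which speeds up the
#'   transforms when the analysis band stops well below the native
#'   Nyquist. `NULL` (default) analyses at the native rate.
#' @param seed Seed for the (surrogate-subsampling) RNG.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(bands = frequency_bands(), fmin = 0.005,
                            fmax_fnirs = 4, fmax_rate = 2, f0 = 1,
                            voices = 32L, alpha = 0.05, n_surrogates = 0L,
                            analyses = c("rates", "fnirs_power",
                                         "fnirs_coherence",
                                         "ihr_resp_coherence"),
                            eeg_cardiac_removal = TRUE, window = NULL,
                            window_offset = 0, rate_fs = 20,
                            fs_analysis = NULL, seed = 1L) {
  known <- c("rates", "fnirs_power", "fnirs_coherence",
             "ihr_resp_coherence", "fnirs_eeg_coherence")
  bad <- setdiff(analyses, known)
  if (length(bad))
    stop("unknown analyses: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.unsorted(bands$fmin) || any(bands$fmax[-nrow(bands)] >
                                     bands$fmin[-1L] + 1e-12))
    stop("bands must be ordered and non-overlapping", call. = FALSE)
  structure(as.list(environment())[names(formals())],
            class = "analysis_config")
}

# detrend + zero-phase bandpass + optional window + optional resampling
# to the configured analysis rate, per class profile
.condition <- function(ts, class, config) {
  fsa <- config$fs_analysis
  if (class %in% c("fnirs", "eeg") && !is.null(fsa) && fsa < ts$fs)
    ts <- resample_ts(ts, fsa)         # anti-aliased; filtering is cheaper
  prof <- preprocess_profile(class, ts$fs)
  out <- bandpass_zerophase(detrend_poly(ts), prof$f_lo, prof$f_hi)
  if (!is.null(config$window))
    out <- ts_window(out, config$window, config$window_offset)
  out
}

# trim ts2 so both series start at (approximately) the same time and
# cover the same duration; both must share fs
.align_pair <- function(ts1, ts2) {
  stopifnot(isTRUE(all.equal(ts1$fs, ts2$fs)))
  t_lo <- max(ts1$t0, ts2$t0)
  t_hi <- min(ts1$t0 + ts_duration(ts1), ts2$t0 + ts_duration(ts2))
  if (t_hi - t_lo < 2 / ts1$fs) stop("no overlap", call. = FALSE)
  list(ts_window(ts1, t_hi - t_lo, t_lo - ts1$t0),
       ts_window(ts2, t_hi - t_lo, t_lo - ts2$t0))
}

# all-pairs coherence curves for one subject in one pass: per frequency,
# the Gram matrix of the (COI-windowed) unit phasors gives the resultant
# of every channel pair at once via one complex matrix product.
# Zero-amplitude phasors (flagged NA upstream) are excluded from averages
# only when a whole row is empty; isolated zero coefficients do not occur
# away from identically zero signals.
.pairwise_coherence_curves <- function(pha, phb = NULL) {
  cross <- !is.null(phb)
  all_ph <- c(pha, if (cross) phb)
  nf <- nrow(pha[[1L]]$U)
  nt <- min(vapply(all_ph, function(p) ncol(p$U), 1L))
  lo <- pha[[1L]]$rng[, "lo"]
  hi <- pmin(pha[[1L]]$rng[, "hi"], nt)
  zero_na <- function(p) {
    u <- p$U[, seq_len(nt), drop = FALSE]
    u[is.na(u)] <- 0
    u
  }
  Ua <- lapply(pha, zero_na)
  Ub <- if (cross) lapply(phb, zero_na) else Ua
  na_ <- length(Ua); nb_ <- length(Ub)
  if (cross) {
    npair <- na_ * nb_
  } else {
    cmb <- utils::combn(na_, 2L)
    npair <- ncol(cmb)
  }
  R <- matrix(NA_real_, npair, nf)
  for (k in seq_len(nf)) {
    if (lo[k] > hi[k]) next
    idx <- lo[k]:hi[k]
    Ma <- vapply(Ua, function(u) u[k, idx], complex(length(idx)))
    Mb <- if (cross) vapply(Ub, function(u) u[k, idx],
                            complex(length(idx))) else Ma
    G <- Mod(t(Conj(Ma)) %*% Mb) / length(idx)
    # cross pairs enumerate the first montage fastest (column-major)
    R[, k] <- if (cross) as.vector(G) else G[t(cmb)]
  }
  R
}

.band_values <- function(curve, grid, bands) {
  vapply(seq_len(nrow(bands)), function(i) {
    sel <- grid$freqs >= bands$fmin[i] & grid$freqs < bands$fmax[i]
    if (!any(sel)) return(NA_real_)
    v <- curve[sel]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1L))
}

#' Run the full cohort analysis
#'
#' Per subject: condition each modality (cubic detrend, zero-phase
#' bandpass, common analysis window); build IHR/IRR series from ECG and
#' respiration-effort peaks; compute Morlet transforms, band-averaged
#' power per fNIRS probe, band-averaged phase coherence for every unique
#' fNIRS pair (global coherence per band), IHR~respiration coherence, and
#' optionally every EEG x fNIRS pair. Surrogate thresholds (when
#' `n_surrogates > 0`) convert coherence to effective coherence before
#' band averaging. Group comparisons then use the Wilcoxon rank-sum test
#' with rank-based effect sizes and the binomial multiple-comparison gate
#' per test family. Subjects missing a modality are dropped from the
#' affected analyses with a logged reason, so each table carries its own
#' N.
#'
#' @param cohort A `cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param config An [analysis_config()].
#' @return Object of class `run_report`: list of result tables
#'   (`rates`, `rate_comparison`, `power_by_probe`, `power_comparison`,
#'   `global_coherence`, `coherence_comparison`, `nvcoherence_pairs`,
#'   `nv_comparison`, `ihr_resp`), the `exclusions` log, and `provenance`.
#' @export
run_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "analysis_config"))
  set.seed(config$seed)
  subjects <- cohort$subjects
  groups <- unname(vapply(subjects, function(s) s$group, ""))
  n <- length(subjects)
  bands <- config$bands
  excl <- list()
  note_excl <- function(id, analysis, reason)
    excl[[length(excl) + 1L]] <<- data.frame(
      id = id, analysis = analysis, reason = reason,
      stringsAsFactors = FALSE)
  tables <- list()

  ## ---- cardiorespiratory rates -------------------------------------
  rate_series <- list()
  if (any(c("rates", "ihr_resp_coherence") %in% config$analyses)) {
    for (k in seq_len(n)) {
      s <- subjects[[k]]
      for (mod in c("ecg", "resp")) {
        raw <- if (mod == "ecg") s$ecg else s$resp
        src <- if (mod == "ecg") "ecg" else "respiration"
        if (is.null(raw)) {
          note_excl(s$id, paste0("rates/", src), "channel missing")
          next
        }
        rate <- tryCatch({
          prof <- preprocess_profile(src, raw$fs)
          r100 <- if (!isTRUE(all.equal(raw$fs, prof$fs_analysis)))
            resample_ts(raw, prof$fs_analysis) else raw
          if (!is.null(config$window))
            r100 <- ts_window(r100, config$window, config$window_offset)
          ev <- detect_peaks(r100, source = src)
          build_rate(ev, fs_out = config$rate_fs)
        }, error = function(e) {
          note_excl(s$id, paste0("rates/", src), conditionMessage(e))
          NULL
        })
        rate_series[[paste(s$id, src, sep = ".")]] <- rate
      }
    }
    rate_rows <- list()
    for (k in seq_len(n)) {
      s <- subjects[[k]]
      for (src in c("ecg", "respiration")) {
        r <- rate_series[[paste(s$id, src, sep = ".")]]
        if (is.null(r)) next
        sm <- rate_summary(r)
        rate_rows[[length(rate_rows) + 1L]] <- data.frame(
          id = s$id, group = s$group, source = src,
          mean_rate = sm$mean, sd_rate = sm$sd, stringsAsFactors = FALSE)
      }
    }
    tables$rates <- do.call(rbind, rate_rows)
    if (!is.null(tables$rates)) {
      cmp <- list()
      for (src in unique(tables$rates$source)) {
        for (metric in c("mean_rate", "sd_rate")) {
          d <- tables$rates[tables$rates$source == src, ]
          a <- d[[metric]][d$group == "patient"]
          b <- d[[metric]][d$group == "control"]
          if (sum(!is.na(a)) < 4L || sum(!is.na(b)) < 4L) next
          row <- compare_groups(a, b)
          cmp[[length(cmp) + 1L]] <- cbind(
            data.frame(analysis = "rates", source = src, metric = metric,
                       stringsAsFactors = FALSE), row)
        }
      }
      tables$rate_comparison <- do.call(rbind, cmp)
    }
  }

  ## ---- fNIRS transforms, power, coherence --------------------------
  need_fnirs <- any(c("fnirs_power", "fnirs_coherence",
                      "fnirs_eeg_coherence") %in% config$analyses)
  if (need_fnirs) {
    probe_names <- names(subjects[[1L]]$fnirs)
    keep_phasors <- any(c("fnirs_coherence", "fnirs_eeg_coherence") %in%
                          config$analyses)
    phasors <- if (keep_phasors) vector("list", n)
    power_rows <- list(); grid_ref <- NULL
    for (k in seq_len(n)) {
      s <- subjects[[k]]
      if (!length(s$fnirs)) {
        note_excl(s$id, "fnirs", "no fNIRS channels")
        next
      }
      ph_k <- list()
      for (nm in names(s$fnirs)) {
        ts <- .condition(s$fnirs[[nm]], "fnirs", config)
        wt <- morlet_wt(ts, fmin = config$fmin,
                        fmax = min(config$fmax_fnirs, 0.45 * ts$fs),
                        f0 = config$f0, voices = config$voices)
        grid_ref <- wt$grid
        if ("fnirs_power" %in% config$analyses) {
          ps <- time_avg_power(wt)
          bv <- .band_values(ps$power, wt$grid, bands)
          power_rows[[length(power_rows) + 1L]] <- data.frame(
            id = s$id, group = s$group, probe = nm, band = bands$band,
            power = bv, stringsAsFactors = FALSE)
        }
        if (keep_phasors) ph_k[[nm]] <- .unit_phasors(wt)
      }
      if (keep_phasors) phasors[[k]] <- ph_k
    }
    if ("fnirs_power" %in% config$analyses) {
      tables$power_by_probe <- do.call(rbind, power_rows)
      cmp <- list()
      for (bd in bands$band) {
        d <- tables$power_by_probe[tables$power_by_probe$band == bd, ]
        pvals <- c(); rows <- list()
        for (pr in probe_names) {
          a <- d$power[d$probe == pr & d$group == "patient"]
          b <- d$power[d$probe == pr & d$group == "control"]
          if (sum(!is.na(a)) < 4L || sum(!is.na(b)) < 4L) next
          row <- compare_groups(a, b)
          rows[[pr]] <- cbind(data.frame(analysis = "fnirs_power",
                                         band = bd, probe = pr,
                                         stringsAsFactors = FALSE), row)
          pvals <- c(pvals, row$p_raw)
        }
        if (!length(rows)) next
        gate <- multiple_comparison_gate(pvals, config$alpha)
        out <- do.call(rbind, rows)
        out$p_bh <- gate$p_bh
        out$significant <- gate$significant
        out$gate_prob <- attr(gate, "gate_prob")
        out$findings <- attr(gate, "findings")
        cmp[[bd]] <- out
      }
      tables$power_comparison <- do.call(rbind, cmp)
      rownames(tables$power_comparison) <- NULL
    }

    if ("fnirs_coherence" %in% config$analyses) {
      pairs <- channel_pairs(probe_names)
      have <- which(!vapply(phasors, is.null, TRUE))
      # per subject x pair x band effective (or raw) band coherence
      glob_rows <- list()
      band_acc <- array(NA_real_, c(length(have), nrow(pairs),
                                    nrow(bands)))
      for (ii in seq_along(have)) {
        k <- have[ii]
        if (config$n_surrogates > 0L) {
          for (pp in seq_len(nrow(pairs))) {
            p1 <- phasors[[k]][[pairs$ch1[pp]]]
            p2 <- phasors[[k]][[pairs$ch2[pp]]]
            core <- .wpc_core(p1, p2)
            st <- inter_subject_threshold(
              lapply(phasors[have], `[[`, pairs$ch1[pp]),
              lapply(phasors[have], `[[`, pairs$ch2[pp]),
              subject = ii, n_surrogates = config$n_surrogates)
            band_acc[ii, pp, ] <- .band_values(core$R - st$thresh,
                                               grid_ref, bands)
          }
        } else {
          Rp <- .pairwise_coherence_curves(phasors[[k]][probe_names])
          for (pp in seq_len(nrow(pairs)))
            band_acc[ii, pp, ] <- .band_values(Rp[pp, ], grid_ref, bands)
        }
      }
      for (ii in seq_along(have)) {
        k <- have[ii]
        for (bi in seq_len(nrow(bands))) {
          vals <- stats::setNames(band_acc[ii, , bi], pairs$pair)
          if (all(is.na(vals))) next
          glob_rows[[length(glob_rows) + 1L]] <- data.frame(
            id = subjects[[k]]$id, group = groups[k],
            band = bands$band[bi],
            global_coherence = global_coherence(vals, probe_names),
            stringsAsFactors = FALSE)
        }
      }
      tables$global_coherence <- do.call(rbind, glob_rows)
      gc_tab <- tables$global_coherence
      rows <- list(); pvals <- c()
      for (bd in bands$band) {
        a <- gc_tab$global_coherence[gc_tab$band == bd &
                                       gc_tab$group == "patient"]
        b <- gc_tab$global_coherence[gc_tab$band == bd &
                                       gc_tab$group == "control"]
        if (sum(!is.na(a)) < 4L || sum(!is.na(b)) < 4L) next
        row <- compare_groups(a, b)
        rows[[bd]] <- cbind(data.frame(analysis = "fnirs_global_coherence",
                                       band = bd, stringsAsFactors = FALSE),
                            row)
        pvals <- c(pvals, row$p_raw)
      }
      if (length(rows)) {
        gate <- multiple_comparison_gate(pvals, config$alpha)
        out <- do.call(rbind, rows)
        out$p_bh <- gate$p_bh
        out$significant <- gate$significant
        out$gate_prob <- attr(gate, "gate_prob")
        out$findings <- attr(gate, "findings")
        rownames(out) <- NULL
        tables$coherence_comparison <- out
      }
    }

    ## ---- EEG x fNIRS coherence -------------------------------------
    if ("fnirs_eeg_coherence" %in% config$analyses) {
      eeg_names <- names(subjects[[1L]]$eeg)
      xp <- cross_pairs(eeg_names, probe_names)
      have <- which(!vapply(phasors, is.null, TRUE))
      pair_rows <- list()
      eeg_ph <- vector("list", n)
      for (k in have) {
        s <- subjects[[k]]
        if (!length(s$eeg)) { note_excl(s$id, "fnirs_eeg", "no EEG"); next }
        ph_e <- list()
        for (nm in eeg_names) {
          ts <- .condition(s$eeg[[nm]], "eeg", config)
          if (config$eeg_cardiac_removal)
            ts <- suppressWarnings(remove_cardiac_artifact(
              ts, cardiac_band = c(0.6, min(1.7, 0.4 * ts$fs))))
          wt <- morlet_wt(ts, fmin = config$fmin,
                          fmax = min(config$fmax_fnirs, 0.45 * ts$fs),
                          f0 = config$f0, voices = config$voices)
          ph_e[[nm]] <- .unit_phasors(wt)
        }
        eeg_ph[[k]] <- ph_e
      }
      have_e <- which(!vapply(eeg_ph, is.null, TRUE))
      for (k in have_e) {
        Rp <- if (config$n_surrogates > 0L) NULL else
          .pairwise_coherence_curves(eeg_ph[[k]][eeg_names],
                                     phasors[[k]][probe_names])
        for (pp in seq_len(nrow(xp))) {
          if (config$n_surrogates > 0L) {
            core <- .wpc_core(eeg_ph[[k]][[xp$ch1[pp]]],
                              phasors[[k]][[xp$ch2[pp]]])
            idx <- match(k, have_e)
            st <- inter_subject_threshold(
              lapply(eeg_ph[have_e], `[[`, xp$ch1[pp]),
              lapply(phasors[have_e], `[[`, xp$ch2[pp]),
              subject = idx, n_surrogates = config$n_surrogates)
            curve <- core$R - st$thresh
          } else {
            curve <- Rp[pp, ]
          }
          bv <- .band_values(curve, grid_ref, bands)
          pair_rows[[length(pair_rows) + 1L]] <- data.frame(
            id = subjects[[k]]$id, group = groups[k], pair = xp$pair[pp],
            band = bands$band, coherence = bv, stringsAsFactors = FALSE)
        }
      }
      tables$nvcoherence_pairs <- do.call(rbind, pair_rows)
      if (!is.null(tables$nvcoherence_pairs)) {
        cmp <- list()
        for (bd in bands$band) {
          d <- tables$nvcoherence_pairs[tables$nvcoherence_pairs$band == bd, ]
          rows <- list(); pvals <- c()
          for (pr in xp$pair) {
            a <- d$coherence[d$pair == pr & d$group == "patient"]
            b <- d$coherence[d$pair == pr & d$group == "control"]
            if (sum(!is.na(a)) < 4L || sum(!is.na(b)) < 4L) next
            row <- compare_groups(a, b)
            rows[[pr]] <- cbind(data.frame(analysis = "fnirs_eeg_coherence",
                                           band = bd, pair = pr,
                                           stringsAsFactors = FALSE), row)
            pvals <- c(pvals, row$p_raw)
          }
          if (!length(rows)) next
          gate <- multiple_comparison_gate(pvals, config$alpha)
          out <- do.call(rbind, rows)
          out$p_bh <- gate$p_bh
          out$significant <- gate$significant
          out$gate_prob <- attr(gate, "gate_prob")
          out$findings <- attr(gate, "findings")
          cmp[[bd]] <- out
        }
        tables$nv_comparison <- do.call(rbind, cmp)
        rownames(tables$nv_comparison) <- NULL
      }
    }
  }

  ## ---- IHR ~ respiration coherence ---------------------------------
  if ("ihr_resp_coherence" %in% config$analyses) {
    rows <- list()
    for (k in seq_len(n)) {
      s <- subjects[[k]]
      ihr <- rate_series[[paste(s$id, "ecg", sep = ".")]]
      if (is.null(ihr) || is.null(s$resp)) {
        note_excl(s$id, "ihr_resp_coherence", "IHR or respiration missing")
        next
      }
      resp20 <- resample_ts(.condition(s$resp, "respiration", config),
                            config$rate_fs)
      ihr_f <- bandpass_zerophase(detrend_poly(ihr), 0.005,
                                  min(2, 0.45 * ihr$fs))
      pairts <- tryCatch(.align_pair(ihr_f, resp20),
                         error = function(e) NULL)
      if (is.null(pairts)) {
        note_excl(s$id, "ihr_resp_coherence", "no overlap")
        next
      }
      dur <- ts_duration(pairts[[1L]])
      fmin_k <- max(config$fmin, 2 * sqrt(2) * config$f0 / dur * 1.05)
      wt1 <- morlet_wt(pairts[[1L]], fmin = fmin_k,
                       fmax = min(config$fmax_rate, 0.45 * config$rate_fs),
                       f0 = config$f0, voices = config$voices)
      wt2 <- morlet_wt(pairts[[2L]], fmin = fmin_k,
                       fmax = min(config$fmax_rate, 0.45 * config$rate_fs),
                       f0 = config$f0, voices = config$voices)
      cs <- wpc(wt1, wt2)
      bv <- .band_values(cs$wpc, cs$grid, bands)
      rows[[length(rows) + 1L]] <- data.frame(
        id = s$id, group = s$group, band = bands$band, coherence = bv,
        stringsAsFactors = FALSE)
    }
    tables$ihr_resp <- do.call(rbind, rows)
  }

  excl_df <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id = character(), analysis = character(),
               reason = character(), stringsAsFactors = FALSE)
  structure(
    list(tables = tables, exclusions = excl_df,
         provenance = list(
           seed = config$seed, alpha = config$alpha,
           n_subjects = n,
           n_patient = sum(groups == "patient"),
           n_control = sum(groups == "control"),
           analyses = config$analyses,
           n_surrogates = config$n_surrogates,
           voices = config$voices, fmin = config$fmin,
           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  tables:",
      paste(names(x$tables), collapse = ", "), "\n  subjects:",
      x$provenance$n_subjects, sprintf("(%d patient / %d control)",
                                       x$provenance$n_patient,
                                       x$provenance$n_control),
      "\n  exclusions:", nrow(x$exclusions), "\n")
  invisible(x)
}

#' Write a run report to CSV tables
#'
#' Writes each result table as CSV (`power_by_probe.csv`,
#' `global_coherence.csv`, `nvcoherence_pairs.csv`,
#' `group_comparison.csv` combining all comparison tables, `rates.csv`,
#' `exclusions.csv`) plus a `run_report.json` provenance file.
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tabs <- report$tables
  emit <- function(d, f) if (!is.null(d))
    utils::write.csv(d, file.path(outdir, f), row.names = FALSE)
  emit(tabs$rates, "rates.csv")
  emit(tabs$power_by_probe, "power_by_probe.csv")
  emit(tabs$global_coherence, "global_coherence.csv")
  emit(tabs$nvcoherence_pairs, "nvcoherence_pairs.csv")
  emit(tabs$ihr_resp, "ihr_resp_coherence.csv")
  comp <- list()
  for (nm in c("rate_comparison", "power_comparison",
               "coherence_comparison", "nv_comparison")) {
    d <- tabs[[nm]]
    if (is.null(d)) next
    for (col in c("band", "probe", "pair", "source", "metric"))
      if (is.null(d[[col]])) d[[col]] <- NA
    comp[[nm]] <- d[, c("analysis", "band", "probe", "pair", "source",
                        "metric", "n_a", "n_b", "median_a", "median_b",
                        "p_raw", "z", "effect_size_d",
                        intersect(c("p_bh", "significant", "gate_prob",
                                    "findings"), names(d)))]
  }
  if (length(comp)) {
    allcols <- Reduce(union, lapply(comp, names))
    comp <- lapply(comp, function(d) {
      for (m in setdiff(allcols, names(d))) d[[m]] <- NA
      d[, allcols]
    })
    utils::write.csv(do.call(rbind, comp),
                     file.path(outdir, "group_comparison.csv"),
                     row.names = FALSE)
  }
  emit(report$exclusions, "exclusions.csv")
  jsonlite::write_json(report$provenance,
                       file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
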