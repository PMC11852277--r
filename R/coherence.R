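# unit phasors of a wavelet transform plus its per-frequency COI column
# range; the representation all coherence computations run on. Amplitude is
# discarded up front, which is what makes phase coherence amplitude-blind.
.unit_phasors <- function(wt) {
  stopifnot(inherits(wt, "wavelet_transform"))
  a <- Mod(wt$coeffs)
  U <- wt$coeffs / a                     # 0/0 -> NaN, flagged NA below
  if (anyNA(U)) U[is.na(U)] <- NA_complex_
  list(U = U, rng = .coi_range(wt), grid = wt$grid, fs = wt$fs,
       label = wt$label)
}

.check_same_grid <- function(g1, g2) {
  if (length(g1$freqs) != length(g2$freqs) ||
      max(abs(g1$freqs - g2$freqs)) > 1e-9 * max(g1$freqs))
    stop("wavelet transforms do not share a frequency grid", call. = FALSE)
}

# resultant vector per frequency over the joint COI of two phasor sets.
# The resultant is computed from per-row cumulative sums of the phasor
# products, so the whole spectrum costs O(nf * nt) with no R-level inner
# loop; circular phase statistics (quartiles) are only computed on request.
.wpc_core <- function(p1, p2, need_phase = FALSE) {
  .check_same_grid(p1$grid, p2$grid)
  nt <- min(ncol(p1$U), ncol(p2$U))
  nf <- nrow(p1$U)
  lo <- pmax(p1$rng[, "lo"], p2$rng[, "lo"])
  hi <- pmin(pmin(p1$rng[, "hi"], p2$rng[, "hi"]), nt)
  Z <- p1$U[, seq_len(nt), drop = FALSE] *
    Conj(p2$U[, seq_len(nt), drop = FALSE])
  nas <- is.na(Z)
  if (any(nas)) Z[nas] <- 0
  # per-row column mask: length-nf bounds recycle down columns, so the
  # comparison applies each row's own COI range
  cl <- col(Z)
  M <- cl >= lo & cl <= hi
  if (any(nas)) M <- M & !nas
  cnt <- rowSums(M)
  tot <- rowSums(Z * M)
  m <- tot / cnt
  R <- Mod(m)
  R[cnt == 0L] <- NA_real_
  mu <- rep(NA_real_, nf)
  q25 <- rep(NA_real_, nf); q75 <- rep(NA_real_, nf)
  if (need_phase) {
    for (k in seq_len(nf)) {
      if (cnt[k] == 0L || !is.finite(R[k]) || R[k] <= 0) next
      mu[k] <- Arg(m[k])
      z <- Z[k, lo[k]:hi[k]]
      z <- z[z != 0]
      dev <- Arg(z * Conj(m[k] / Mod(m[k])))  # wrapped deviation from mean
      qq <- stats::quantile(dev, c(0.25, 0.75), names = FALSE, type = 7)
      q25[k] <- mu[k] + qq[1L]; q75[k] <- mu[k] + qq[2L]
    }
  }
  list(R = R, mu = mu, q25 = q25, q75 = q75, n_times = as.integer(cnt),
       grid = p1$grid)
}

#' Wavelet phase coherence between two transforms
#'
#' Quantifies, per frequency, how constant the phase difference between two
#' signals stays over time. With `Delta-theta(t, k)` the instantaneous phase
#' difference, the coherence is the circular resultant length
#' `R = sqrt(<cos Dth>^2 + <sin Dth>^2)`, the averages running over all
#' times inside the joint cone of influence. `R` lies in `[0, 1]` and
#' equals 1 exactly when the phase difference never varies; it is
#' completely independent of either signal's amplitude. The squared
#' convention `R^2` is available via `convention = "squared"`.
#'
#' @param wt1,wt2 `wavelet_transform` objects on the same grid and
#'   sampling frequency (records may differ in length; the overlap is
#'   used).
#' @param convention `"resultant"` (default) or `"squared"`.
#' @return Object of class `coherence_spectrum`: list with `wpc`,
#'   `phase_mean` (circular mean of the phase difference, radians,
#'   oscillator 1 minus oscillator 2), `phase_q25`/`phase_q75` (circular
#'   25th/75th percentiles about the mean), `n_times`, `grid`,
#'   `convention`.
#' @export
wpc <- function(wt1, wt2, convention = c("resultant", "squared")) {
  convention <- match.arg(convention)
  p1 <- if (inherits(wt1, "wavelet_transform")) .unit_phasors(wt1) else wt1
  p2 <- if (inherits(wt2, "wavelet_transform")) .unit_phasors(wt2) else wt2
  core <- .wpc_core(p1, p2, need_phase = TRUE)
  if (all(core$n_times == 0L))
    stop("no overlapping edge-unaffected samples at any frequency",
         call. = FALSE)
  val <- if (convention == "squared") core$R^2 else core$R
  structure(
    list(wpc = val, phase_mean = core$mu, phase_q25 = core$q25,
         phase_q75 = core$q75, n_times = core$n_times, grid = core$grid,
         convention = convention,
         labels = c(p1$label, p2$label)),
    class = "coherence_spectrum"
  )
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %s ~ %s: %d frequencies, %g-%g Hz\n",
              x$labels[1L], x$labels[2L], length(x$wpc),
              min(x$grid$freqs), max(x$grid$freqs)))
  invisible(x)
}

#' @export
plot.coherence_spectrum <- function(x, ...) {
  graphics::plot(x$grid$freqs, x$wpc, type = "l", log = "x", ylim = c(0, 1),
                 xlab = "Frequency (Hz)", ylab = "Phase coherence",
                 main = paste(x$labels, collapse = " ~ "), ...)
  invisible(x)
}

#' Inter-subject surrogate significance threshold
#'
#' Coherence between the same channel pair taken from two *different*
#' subjects can only be coincidental, so the distribution of such
#' inter-subject coherences provides a per-frequency significance null.
#' For subject `i` and channel pair (a, b) the surrogate set is the
#' coherence of subject i's channel a with every other subject's channel
#' b, and of subject i's channel b with every other subject's channel a
#' (`2(N-1)` pairings); the threshold is the 95th percentile (by default)
#' of these surrogate coherences at each frequency. Records are truncated
#' to the common overlap.
#'
#' @param wts_a,wts_b Lists of `wavelet_transform` objects (one per
#'   subject, same subject order, shared grid). For a same-channel
#'   analysis pass the same list twice.
#' @param subject Index of the subject the threshold is for.
#' @param prob Percentile (default 0.95).
#' @param n_surrogates Optional cap on the number of surrogate pairings;
#'   a random subset is drawn (seed the session for reproducibility).
#' @param convention Passed through to the coherence computation.
#' @return Object of class `surrogate_threshold`: list with `thresh`
#'   (per-frequency), `prob`, `n_surrogates`, `scheme`, `grid`.
#' @export
inter_subject_threshold <- function(wts_a, wts_b, subject, prob = 0.95,
                                    n_surrogates = NULL,
                                    convention = c("resultant", "squared")) {
  convention <- match.arg(convention)
  stopifnot(length(wts_a) == length(wts_b))
  N <- length(wts_a)
  others <- setdiff(seq_len(N), subject)
  pairings <- rbind(
    cbind(a_subj = subject, b_subj = others),
    cbind(a_subj = others, b_subj = subject)
  )
  if (!is.null(n_surrogates) && n_surrogates < nrow(pairings))
    pairings <- pairings[sample.int(nrow(pairings), n_surrogates), ,
                         drop = FALSE]
  if (nrow(pairings) < 8L)
    stop(sprintf(paste0("only %d surrogate pairings available; at least 8 ",
                        "needed for a stable percentile"), nrow(pairings)),
         call. = FALSE)
  prep <- function(x) if (inherits(x, "wavelet_transform"))
    .unit_phasors(x) else x
  pa <- lapply(wts_a, prep); pb <- lapply(wts_b, prep)
  vals <- matrix(NA_real_, nrow(pairings), length(pa[[1L]]$grid$freqs))
  for (s in seq_len(nrow(pairings))) {
    core <- .wpc_core(pa[[pairings[s, "a_subj"]]],
                      pb[[pairings[s, "b_subj"]]])
    vals[s, ] <- if (convention == "squared") core$R^2 else core$R
  }
  thresh <- apply(vals, 2L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::quantile(v, prob, names = FALSE)
  })
  structure(list(thresh = thresh, prob = prob, n_surrogates = nrow(pairings),
                 scheme = "inter-subject, both channel orientations",
                 grid = pa[[1L]]$grid),
            class = "surrogate_threshold")
}

#' Effective coherence
#'
#' Pointwise subtraction of a surrogate significance threshold from a
#' coherence spectrum. Negative values are retained (no clipping): group
#' statistics operate on the signed values.
#'
#' @param cs A `coherence_spectrum`.
#' @param st A `surrogate_threshold` on the same grid.
#' @return Object of class `effective_coherence`: list with `effective`,
#'   `wpc`, `thresh`, `grid`.
#' @export
effective_coherence <- function(cs, st) {
  stopifnot(inherits(cs, "coherence_spectrum"),
            inherits(st, "surrogate_threshold"))
  .check_same_grid(cs$grid, st$grid)
  structure(list(effective = cs$wpc - st$thresh, wpc = cs$wpc,
                 thresh = st$thresh, phase_mean = cs$phase_mean,
                 grid = cs$grid, labels = cs$labels),
            class = "effective_coherence")
}

#' Enumerate unique unordered channel pairs
#'
#' @param channels Character vector of channel names.
#' @return `data.frame` with columns `ch1`, `ch2`, `pair` (`"ch1~ch2"`);
#'   `choose(n, 2)` rows.
#' @export
channel_pairs <- function(channels) {
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("duplicated channel names", call. = FALSE)
  idx <- utils::combn(length(channels), 2L)
  data.frame(ch1 = channels[idx[1L, ]], ch2 = channels[idx[2L, ]],
             pair = paste0(channels[idx[1L, ]], "~", channels[idx[2L, ]]),
             stringsAsFactors = FALSE)
}

#' Enumerate cross-modal channel pairs
#'
#' @param channels_a,channels_b Character vectors (e.g. EEG and fNIRS
#'   montages).
#' @return `data.frame` with columns `ch1`, `ch2`, `pair`;
#'   `length(a) * length(b)` rows.
#' @export
cross_pairs <- function(channels_a, channels_b) {
  g <- expand.grid(ch1 = as.character(channels_a),
                   ch2 = as.character(channels_b),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$pair <- paste0(g$ch1, "~", g$ch2)
  g
}

#' Global coherence of a montage
#'
#' The average band coherence over all unique unordered channel pairs of a
#' montage (coherence is symmetric in its two arguments, so ordered
#' duplicates carry no information). An 11-probe montage yields 55 pairs.
#'
#' @param pair_values Named numeric vector (names `"A~B"`) or `data.frame`
#'   with columns `ch1`, `ch2`, `value`: one band-averaged (effective)
#'   coherence value per unique pair for one subject.
#' @param channels Channel names of the montage; completeness is enforced
#'   and missing pairs are reported by name.
#' @return Scalar mean over the `choose(n, 2)` pairs.
#' @export
global_coherence <- function(pair_values, channels) {
  want <- channel_pairs(channels)
  if (is.data.frame(pair_values)) {
    have <- paste0(pair_values$ch1, "~", pair_values$ch2)
    vals <- pair_values$value
  } else {
    have <- names(pair_values)
    vals <- as.numeric(pair_values)
  }
  # accept either orientation of each pair name
  flip <- function(p) vapply(strsplit(p, "~", fixed = TRUE),
                             function(x) paste0(x[2L], "~", x[1L]), "")
  idx <- match(want$pair, have)
  idx[is.na(idx)] <- match(flip(want$pair[is.na(idx)]), have)
  if (anyNA(idx))
    stop("missing pairs: ", paste(want$pair[is.na(idx)], collapse = ", "),
         call. = FALSE)
  mean(vals[idx])
}

#' Time lag implied by a phase difference
#'
#' Converts a circular-mean phase difference at frequency `f` into a time
#' lag `tau = Delta-theta / (2 pi f)`. With the phase difference defined as
#' oscillator 1 minus oscillator 2, a negative lag means oscillator 2
#' precedes oscillator 1.
#'
#' @param phase A `coherence_spectrum` (its circular-mean phase difference
#'   at the grid frequency nearest `f` is used) or a numeric phase
#'   difference in radians.
#' @param f Frequency in Hz.
#' @return Lag in seconds (`NA` where the phase is undefined).
#' @export
estimate_time_lag <- function(phase, f) {
  stopifnot(is.numeric(f), all(f > 0))
  if (inherits(phase, "coherence_spectrum") ||
      inherits(phase, "effective_coherence")) {
    k <- vapply(f, function(fi) which.min(abs(phase$grid$freqs - fi)), 1L)
    dth <- phase$phase_mean[k]
  } else {
    dth <- as.numeric(phase)
  }
  dth / (2 * pi * f)
}
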