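#' Two-sided Wilcoxon rank-sum test with standard score
#'
#' Rank-sum test via the normal approximation with tie-corrected variance
#' and no continuity correction. The standard score `z` is returned
#' because the rank-based effect size is computed from it
#' ([effect_size_rank()]). One value per subject per metric must be
#' supplied: data are aggregated before testing so that nesting within
#' subjects never inflates the sample size.
#'
#' @param a,b Numeric vectors (one value per subject), each of length
#'   >= 4.
#' @param min_n Minimum per-group size (default 4).
#' @return List with `p` (two-sided), `z`, `n` (total sample size),
#'   `median_a`, `median_b`.
#' @export
wilcoxon_ranksum <- function(a, b, min_n = 4L) {
  a <- as.numeric(a); b <- as.numeric(b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b); N <- na + nb
  if (na < min_n || nb < min_n)
    stop(sprintf("each group needs >= %d values (got %d, %d)",
                 min_n, na, nb), call. = FALSE)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- na * nb / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (W - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(p = p, z = z, n = N,
       median_a = stats::median(a), median_b = stats::median(b))
}

#' Rank-based effect size (nonparametric Cohen's d)
#'
#' From the rank-sum standard score `z` and total sample size `N`, the
#' correlation-type effect size is `r = z / sqrt(N)` and the Cohen's-d
#' analogue is `d = 2 r / sqrt(1 - r^2)`. The magnitude `|d|` is reported
#' (direction is carried separately by the group medians); 0.5-0.8 is
#' conventionally "medium" and above 0.8 "large".
#'
#' @param z Standard score from [wilcoxon_ranksum()].
#' @param N Total (combined) sample size.
#' @return List with `r`, `d` (absolute value), `magnitude`
#'   (`"small"`/`"medium"`/`"large"`).
#' @examples
#' effect_size_rank(z = 3, N = 36)  # r = 0.5, d = 1.1547
#' @export
effect_size_rank <- function(z, N) {
  stopifnot(is.numeric(z), length(z) == 1L, is.numeric(N), N > 0)
  r <- z / sqrt(N)
  if (abs(r) >= 1)
    stop("degenerate standardization: |z|/sqrt(N) >= 1", call. = FALSE)
  d <- abs(2 * r / sqrt(1 - r^2))
  list(r = r, d = d,
       magnitude = if (d >= 0.8) "large" else if (d >= 0.5) "medium"
                   else "small")
}

#' Expected false rejections under the global null
#'
#' With `n_tests` independent tests at level `alpha` and all null
#' hypotheses true, `n_tests * alpha` rejections are expected by chance
#' (2.75 for a 55-pair montage at alpha 0.05; 8.8 for 176 cross-modal
#' pairs).
#'
#' @param n_tests Number of tests in the family.
#' @param alpha Significance level, in (0, 1).
#' @return `n_tests * alpha`.
#' @export
expected_false_positives <- function(n_tests, alpha) {
  stopifnot(n_tests >= 0, alpha > 0, alpha < 1)
  n_tests * alpha
}

#' Upper tail of the binomial distribution
#'
#' Exact probability of observing `k` or more positive findings among `n`
#' tests when each is positive with probability `p`.
#'
#' @param n Number of tests.
#' @param p Per-test positive probability.
#' @param k Finding count.
#' @return `P(X >= k)` for `X ~ Binomial(n, p)`; exactly 1 when `k <= 0`.
#' @examples
#' binomial_tail(11, 0.05, 2)   # ~0.102
#' binomial_tail(11, 0.05, 4)   # ~0.0016
#' @export
binomial_tail <- function(n, p, k) {
  stopifnot(n >= 0, k <= n, p >= 0, p <= 1)
  if (k <= 0) return(1)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Binomial multiple-comparison gate
#'
#' Decision rule for a family of group comparisons: count the findings
#' (raw `p <= alpha`), compute the exact binomial probability of that many
#' or more findings under the global null, and (a) if that probability
#' exceeds 5%, apply the Benjamini-Hochberg step-up correction and accept
#' only findings whose adjusted p-value stays below `alpha`; (b) otherwise
#' the finding count itself is too unlikely to be chance, and the raw
#' findings are accepted without further correction. The gate probability
#' is reported either way.
#'
#' @param pvalues Raw p-values of the whole family.
#' @param alpha Per-test significance level (default 0.05).
#' @param gate_level Gate cut-off on the binomial probability (default
#'   0.05).
#' @return `data.frame` with columns `p_raw`, `p_bh` (NA when the gate
#'   made correction unnecessary), `significant`; attributes `findings`,
#'   `gate_prob`, `corrected` (logical).
#' @export
multiple_comparison_gate <- function(pvalues, alpha = 0.05,
                                     gate_level = 0.05) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  findings <- sum(p[ok] <= alpha)
  gate_prob <- binomial_tail(sum(ok), alpha, findings)
  if (gate_prob > gate_level) {
    p_bh <- rep(NA_real_, length(p))
    p_bh[ok] <- stats::p.adjust(p[ok], method = "BH")
    significant <- !is.na(p_bh) & p_bh <= alpha
    corrected <- TRUE
  } else {
    p_bh <- rep(NA_real_, length(p))
    significant <- ok & p <= alpha
    corrected <- FALSE
  }
  out <- data.frame(p_raw = p, p_bh = p_bh, significant = significant)
  attr(out, "findings") <- findings
  attr(out, "gate_prob") <- gate_prob
  attr(out, "corrected") <- corrected
  out
}

#' Per-frequency group comparison of spectral curves
#'
#' Wilcoxon rank-sum test at every grid frequency on subject-level curve
#' values (power or coherence), marking frequencies with uncorrected
#' `p <= alpha` -- the per-frequency significance trace drawn along the
#' x-axis of group median spectra.
#'
#' @param curves_a,curves_b Numeric matrices, subjects x frequencies, on a
#'   shared grid; each group needs >= 4 subjects.
#' @param freqs Optional grid frequencies (returned alongside).
#' @param alpha Mark level (default 0.05, uncorrected).
#' @return `data.frame` with columns `freq` (if given), `p`, `z`,
#'   `marked`.
#' @export
pointwise_frequency_tests <- function(curves_a, curves_b, freqs = NULL,
                                      alpha = 0.05) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  if (ncol(curves_a) != ncol(curves_b))
    stop("curves do not share a grid", call. = FALSE)
  if (nrow(curves_a) < 4L || nrow(curves_b) < 4L)
    stop("each group needs >= 4 subjects", call. = FALSE)
  res <- vapply(seq_len(ncol(curves_a)), function(k) {
    a <- curves_a[, k]; b <- curves_b[, k]
    if (all(is.na(a)) || all(is.na(b))) return(c(NA_real_, NA_real_))
    w <- wilcoxon_ranksum(a, b)
    c(w$p, w$z)
  }, numeric(2L))
  out <- data.frame(p = res[1L, ], z = res[2L, ],
                    marked = !is.na(res[1L, ]) & res[1L, ] <= alpha)
  if (!is.null(freqs)) out <- cbind(data.frame(freq = freqs), out)
  out
}

#' Compare one metric between two groups
#'
#' Convenience wrapper combining [wilcoxon_ranksum()] and
#' [effect_size_rank()] into one row of a group-comparison table.
#'
#' @param a,b Subject-level values for the two groups.
#' @return One-row `data.frame`: `n_a`, `n_b`, `median_a`, `median_b`,
#'   `p_raw`, `z`, `effect_size_d`.
#' @export
compare_groups <- function(a, b) {
  w <- wilcoxon_ranksum(a, b)
  d <- if (abs(w$z) / sqrt(w$n) < 1) effect_size_rank(w$z, w$n)$d
       else Inf
  data.frame(n_a = sum(!is.na(a)), n_b = sum(!is.na(b)),
             median_a = w$median_a, median_b = w$median_b,
             p_raw = w$p, z = w$z, effect_size_d = d)
}
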