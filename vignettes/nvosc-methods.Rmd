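---
title: "Multi-scale oscillatory analysis of neurovascular recordings with nvosc"
author: "nvosc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale oscillatory analysis of neurovascular recordings with nvosc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvosc)
```

## The problem

Resting-state recordings of brain oxygenation (fNIRS oxyhaemoglobin), EEG,
ECG and respiration effort contain spontaneous oscillations spanning more
than two decades of frequency, from cardiac activity near 1 Hz down to
endothelial vasomotion with 100-200 s periods. These rhythms are
time-varying: their instantaneous frequencies wander, which makes plain
Fourier analysis a poor fit and motivates time-frequency methods with
logarithmic frequency resolution. `nvosc` implements the full chain needed
to compare such dynamics between two subject groups (for example a patient
cohort and healthy controls): conditioning, Morlet wavelet transforms,
wavelet phase coherence with inter-subject surrogate significance,
instantaneous heart- and respiration-rate extraction, band-averaged group
statistics, and a synthetic cohort generator that provides ground truth for
every stage.

## Conditioning

Each channel is detrended by subtracting its least-squares cubic polynomial
(`detrend_poly`) and bandpass filtered with a zero-phase Butterworth filter
(`bandpass_zerophase`), by default between 0.005 and 2 Hz. Two numerical
choices matter here:

* The filter is applied as a cascade of order-2 high-pass and low-pass
  sections rather than a single fourth-order bandpass polynomial. With
  corners nearly three decades apart the single-polynomial form is
  numerically ill-conditioned in the backward (zero-phase) pass; the
  cascade is not, and forward-backward application doubles the effective
  order to 4, which remains stable at the extreme 0.005 Hz corner.
* Records are padded by symmetric (even) reflection before filtering, about
  one settling length of the slow corner. Anti-symmetric reflection, a
  common default, inserts a step in the local mean at the pad junction;
  the 0.005 Hz high-pass corner turns that step into a slow transient that
  leaks back into the record tail during the backward pass. Even
  reflection introduces no such step.

fNIRS and EEG channels are analysed up to 4 Hz (capped at 0.45 of the
sampling rate); the upper bandpass corner for these classes follows the same
cap. Resampling (`resample_ts`) is rational-ratio polyphase FIR
interpolation with the anti-alias cutoff at the tighter Nyquist, designed
with `signal::fir1` at 20 taps per phase; the group delay is compensated
exactly so event timing (ECG R-waves) is preserved.

Cardiac electrical activity cross-talks into low-frequency EEG.
`remove_cardiac_artifact` extracts the maximum-amplitude wavelet ridge in
the cardiac band (0.6-1.7 Hz, `f0 = 2`), reconstructs that single mode from
the ridge coefficients, and subtracts it. Harmonics are not modelled: the
artefact addressed is cross-talk at the cardiac fundamental. If the ridge
does not stand at least a factor 2 above the median in-band amplitude the
channel is returned unchanged with a warning, so noise ridges are never
subtracted.

## Wavelet transform

`morlet_wt` computes the continuous wavelet transform with the
admissibility-corrected Morlet mother wavelet on a logarithmic grid
(default 32 voices per octave). The frequency-resolution parameter `f0`
(default 1; 2 for heart-ridge tracking) trades time against frequency
resolution. The transform is normalized so that a stationary unit-amplitude
sinusoid has ridge amplitude 1 — the proportionality constant is exactly 1 —
which pairs with the power convention below. Coefficients within
`sqrt(2) * f0 / f` seconds of either record edge (the e-folding width of
the Gaussian envelope at frequency `f`) are inside the cone of influence
and are excluded from every time average; this is also why all analyses
need records several times longer than the slowest period of interest.

Time-averaged power (`time_avg_power`) is the square of the time-averaged
coefficient amplitude, `(mean |W|)^2`. The more common mean-of-squares
convention `mean(|W|^2)` is available behind `convention = "energy"` but is
not the default; for amplitude-modulated signals the two differ (Jensen's
inequality) and the tests pin the default to the amplitude-then-square
definition.

Ridge extraction (`extract_ridge`) is greedy maximum tracking with a
continuity penalty (5% of the in-band amplitude maximum per grid step,
which suppresses jumps beyond about 3 grid steps per sample), followed by
an unpenalized re-maximization within three grid steps of the smooth
track. The second pass removes the hysteresis a pure penalty tracker shows
on frequency sweeps while retaining jump suppression.

## Phase coherence and surrogates

With instantaneous phases from two transforms, the phase difference field
is `Dth(t, k) = th1 - th2` and the wavelet phase coherence per frequency is
the circular resultant length

\[ R_k = \sqrt{\langle\cos \Delta\theta_k\rangle^2 +
              \langle\sin \Delta\theta_k\rangle^2}, \]

averaged over times inside the joint cone of influence. `R` is 1 exactly
when the phase difference never changes and is independent of both
signals' amplitudes. The squared convention `R^2` — which some displayed
formulations of this quantity read as — is available via
`convention = "squared"`; the default is `R` so the identity case is 1 and
the `[0, 1]` bounds hold on the natural scale.

Because two unrelated signals of finite length always show some spurious
coherence, significance comes from inter-subject surrogates
(`inter_subject_threshold`): coherence between one subject's channel and
every *other* subject's matching channel can only be coincidental. Both
orientations of the channel pair are used, giving `2(N-1)` surrogate
pairings per subject; the per-frequency 95th percentile of these surrogate
coherences is the threshold, and `effective_coherence` subtracts it,
retaining negative values (group statistics operate on the signed values).
The surrogate count is configurable and a random subset can be drawn when
the full set is unnecessarily large. At least 8 pairings are required for
a usable percentile. Note the finite-sample percentile makes the genuine
exceedance rate sit slightly above the nominal 5% (about 6-7% with ~40
surrogates); the calibration test asserts the 2-10% band accordingly.

Global coherence (`global_coherence`) averages a band-averaged coherence
over all unique unordered channel pairs of a montage — 55 pairs for 11
fNIRS probes — and refuses to compute if any pair is missing. A circular-
mean phase difference at frequency `f` converts to a time lag
`tau = Dth / (2 pi f)` (`estimate_time_lag`); negative `tau` means the
second oscillator leads.

## Heart and respiration rates

R-peaks and breath maxima are found by `detect_peaks`: local maxima whose
prominence over a running-median baseline exceeds half the sliding median
of per-window maximum prominences (windows of 10 s for ECG, 60 s for
respiration), a refractory interval (0.25 s / 1 s), and a trough-descent
merge that removes duplicate maxima on broad respiration crests. Peak
times are refined by parabolic interpolation. The instantaneous rate
series (`build_rate`) places anchors at inter-peak midpoints with value
the inverse interval, interpolates linearly onto a 100 Hz grid, and
downsamples to 20 Hz for analysis — a rate series cannot carry information
above half the event rate, so nothing is lost. Rates outside broad
physiological bounds raise warnings, not errors. `crosscheck_rate_with_ridge`
validates peak-derived rates against wavelet ridge frequencies; its median
statistic is deliberately robust, so it flags wholesale misestimation
(halved or doubled rates) rather than sporadic missed beats.

## Group statistics

All comparisons aggregate to one value per subject before testing.
`wilcoxon_ranksum` uses the normal approximation with tie-corrected
variance and no continuity correction; the standard score `z` feeds the
rank-based effect size `r = z / sqrt(N)`, `d = 2r / sqrt(1 - r^2)`
(`effect_size_rank`), reported as a magnitude with direction carried by
the group medians. The approximation tracks the exhaustive permutation
p-value to within a few hundredths for groups of 6 or more and within 0.02
in the decision-relevant region (exact p below 0.1); at 4 subjects per
group the permutation distribution is too coarse for closer agreement,
which is why the per-group minimum is 4 and the tests assert agreement
only qualitatively there.

Multiple comparisons across a family of channels or pairs are handled by
the binomial gate (`multiple_comparison_gate`): if the exact binomial
probability of the observed number of findings (raw p at or below alpha)
under the global null exceeds 5%, the family is Benjamini-Hochberg
corrected and only BH-surviving findings are accepted; otherwise the
finding count itself is evidence and raw findings stand. The expected
false-rejection count `n * alpha` (2.75 for 55 tests, 8.8 for 176) is
reported alongside.

## The synthetic cohort

`generate_cohort` builds a two-group cohort with the statistical structure
the analysis assumes, so every stage can be tested against ground truth.
Defaults are the emulated study conditions: 19 patients and 20 controls,
25-minute records, fNIRS/EEG at 31.25 Hz, ECG and respiration effort at
1200 Hz, respiration near 0.21 Hz (control) versus 0.28 Hz (patient),
heart rate near 1 Hz with respiratory sinus arrhythmia of 0.05 Hz depth.

Per band (one oscillator per cardiovascular band, centred at the band's
geometric-mean frequency) a subject-level phase is integrated from an
instantaneous frequency that wanders as a smooth unit-variance spline
process (timescale 100 s; 60 s for respiration) — honouring the
time-varying-frequency character of these rhythms rather than fixed
sinusoidal FM. Each fNIRS channel receives every band's rhythm through a
*slowly time-varying* phase offset whose standard deviation is the band's
jitter parameter (timescale 30 s): a constant offset would leave phase
coherence at exactly 1, so time-varying jitter is what makes coherence a
controllable, monotonically decreasing function of the jitter level
(approximately `exp(-sigma^2)` for two independently jittered channels).
For the same reason the cardiac component inside fNIRS carries channel
jitter like every other band — with a jitter-free cardiac term both groups
would show cardiac coherence near 1 and no contrast could exist. EEG
channels are 1/f noise plus the band rhythms weighted by neurovascular
coupling `rho` plus jitter-free cardiac electrical cross-talk; the ECG is
a train of 20 ms Gaussian R-waves at integer crossings of the heart phase,
chosen so peak detection is non-trivial but reliable at noise levels up to
about 0.1.

The built-in group contrasts are: reduced patient amplitude in the
myogenic and neurogenic (mildly also endothelial) bands; larger patient
phase jitter in every band, lowering inter-channel coherence across the
board; reduced patient neurovascular coupling in the myogenic and
neurogenic bands; and the respiration-rate difference. What the generator
does *not* emulate: haemodynamic biophysics (no balloon model or optics),
realistic EEG microstructure above the slow bands, movement artefacts, or
clinical heterogeneity. Passing recovery tests therefore shows the
pipeline extracts what the generative model puts in — it does not validate
the physiological interpretation of real recordings.

## Pipeline and problem sizes

`run_analysis` orchestrates the full study analysis and
`write_report`/the `inst/cli/nvosc.R` wrapper serialize it. Determinism is
end-to-end: a config and seed reproduce every table bit for bit. Subjects
missing a modality are dropped from the affected analyses only, with the
reason logged, so each table carries its own N. The 25-minute analysis
window is taken from the record start unless an offset is configured.

The test-suite and acceptance runs use deliberately reduced problem sizes,
chosen once as the package's standard desk-scale configuration: 600 s
records, fNIRS generated at 10 Hz and analysed at 4 Hz (the analysis band
stops at 1.7 Hz, so 4 Hz sampling loses nothing), 6 voices per octave,
ECG at 100 Hz and respiration at 50 Hz, 20 cohort seeds for contrast
recovery and 20 null-cohort seeds (10 + 10 subjects) for gate calibration.
At these sizes the full recovery suite runs in minutes on one CPU while
every qualitative contrast remains overwhelmingly significant
(per-seed Wilcoxon p-values near 1e-7). Users analysing real 25-minute
recordings should keep the defaults (32 voices, native rates) and expect
minutes per subject rather than seconds.

A note on null calibration: the binomial gate and BH correction control
false positives *per family*. A run that reports several families (one per
band for probe-level power, plus the band-level coherence family) will
therefore show at least one accepted finding on a null cohort in roughly
`1 - (1 - r_1)(1 - r_2)...` of runs, where each family's rate `r_i`
combines its gate path (for example `P(X >= 3 | 11, 0.05) = 1.5%` for an
11-probe band) and its BH path (at most about 5% under the Simes bound).
Across the seven families of the standard run this compounds to roughly a
third of null cohorts showing some accepted finding somewhere — the
expected behaviour of per-family error control, not a defect; interpret
findings family by family.

## Known limitations

* Cardiac-artefact removal subtracts the fundamental ridge only; strong
  harmonics of the cardiac mode in EEG survive.
* The surrogate threshold is a finite-sample 95th percentile; with few
  surrogates its exceedance rate under independence is biased a point or
  two above nominal.
* The Wilcoxon layer is asymptotic; exact small-sample inference is out of
  scope (group minimum 4 enforced).
* Effective coherence in the pipeline is opt-in (`n_surrogates > 0`)
  because all-pairs surrogate computation is quadratic in cohort size;
  the standalone `inter_subject_threshold` is the fully general tool.
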