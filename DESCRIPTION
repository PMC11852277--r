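Package: nvosc
Title: Multi-Scale Oscillatory Analysis of Neurovascular Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing slow oscillatory dynamics in multichannel
    neurovascular recordings (fNIRS oxyhaemoglobin, EEG, ECG and respiration
    effort) between subject groups. Implements Morlet continuous wavelet
    transforms on logarithmic frequency grids with cone-of-influence masking,
    time-averaged wavelet power, wavelet phase coherence with inter-subject
    surrogate significance thresholds, instantaneous heart- and
    respiration-rate extraction from peak trains, band-averaged group
    statistics (Wilcoxon rank-sum with rank-based effect sizes, a binomial
    multiple-comparison gate and Benjamini-Hochberg correction), a synthetic
    two-group cohort generator with ground-truth parameters, and an
    end-to-end analysis pipeline with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
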