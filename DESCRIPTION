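Package: ultrarhythm
Title: Detection of Circadian and ~12h Ultradian Rhythms in Short
    Transcriptome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rhythm-inference toolkit for short (24-48h, 2h-interval)
    longitudinal gene-expression time series, as used to detect circadian
    (~24h) and ultradian (~12h) transcriptional rhythms in human blood.
    Provides background-panel expression filtering and detrending, a
    nonparametric cyclic umbrella rank test scanned over periods (a
    RAIN-style scan) in continuous and duplicate modes, matrix-pencil
    decomposition of each gene series into damped sinusoids with
    period/decay classification and dominant-oscillation calls, Fisher's
    method meta-analysis across participants with Benjamini-Hochberg FDR,
    permutation-based FDR by time-label shuffling, harmonic-artifact
    controls, intron-retention rhythm filtering and synchronization
    analysis, cross-species gene-set overlap statistics, preranked
    running-sum gene-set enrichment, and a seeded synthetic-data generator
    reproducing the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
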