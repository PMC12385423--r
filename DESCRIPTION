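Package: dyadsync
Title: Dyadic Neural and Autonomic Synchrony Analysis for Hyperscanning
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-participant ("hyperscanning")
    physiological recordings of collaborative tasks. Computes
    baseline-normalized EEG band-power spectra per region of interest,
    per-phase autonomic features (skin conductance, heart rate, heart rate
    variability) from raw electrodermal and photoplethysmography signals,
    and an inter-member Euclidean-distance synchrony index; fits
    repeated-measures ANOVAs with Greenhouse-Geisser correction and
    Bonferroni post hocs; and performs a validated two-stage (Ward then
    k-means) cluster analysis of heart-rate-variability synchrony with gap
    statistic, silhouette and bootstrap stability indices. Includes a
    synthetic dyad generator with known ground truth so every stage of the
    pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
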