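Package: vasowave
Title: Vasomotion Detection in Laser Speckle Imaging by Wavelet Spectral
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting spontaneous and drug-induced
    vasomotion in laser speckle contrast recordings of the retinal
    vasculature.  Converts raw speckle intensity frames to speckle-variance
    (SV) maps by sliding-window contrast analysis, extracts per-vessel SV
    time series from user regions of interest via masking, centerline
    skeletonization and perpendicular scan-line averaging, computes
    continuous Morlet wavelet energy spectra averaged over protocol windows,
    and quantifies oscillatory activity with peak-prominence statistics
    (energy ratio, prominence ratio, band-wise detection counts and paired
    frequency comparisons).  Includes a synthetic-data generator with
    Gamma-distributed speckle statistics and known ground-truth oscillatory
    content so that every stage is testable without animal recordings.
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
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
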