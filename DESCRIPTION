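Package: whiskerkin
Title: Kinematics and Spectral Analysis of Evoked and Spontaneous Whisker Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for optogenetically evoked whisker movements and
    denervation transcriptomics. Extracts per-response kinematic metrics (peak
    amplitude, peak velocity via Savitzky-Golay smoothed derivatives,
    time-to-peak, half-width, and a persistence index of fatigability) from
    high-speed whisker-angle time series, builds stimulus duration-response
    families and longitudinal group summaries, quantifies 5-8 Hz fasciculation
    band power from variance-normalized periodograms, and compares
    differential-expression tables across tissues (fold-change/q-value filter
    chain, overlap sets, TPM z-score matrices, polar-expression filtering). A
    synthetic-data generator produces whisker-angle sessions and transcript
    tables with known ground truth so the full pipeline is testable without
    raw video or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
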