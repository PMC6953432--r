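Package: neonosc
Title: Discontinuous Neonatal Cortical Activity: Detection, Coupling,
    Morphometry and Robust Group Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for developmental electrophysiology and
    microglia imaging. Detects discontinuous spindle-shaped network
    oscillations in neonatal local field potential recordings from an RMS
    envelope with a Gaussian-fit threshold, computes Welch power spectra over
    concatenated oscillatory windows and optogenetic stimulation modulation
    indices, detects multi-unit spikes from the high-pass band, and measures
    spike-field coupling via pairwise phase consistency and spike-triggered
    relative LFP power. Includes microglia morphometry (counting, shape
    features, 3D hysteresis segmentation, VGLUT1 puncta engulfment), robust
    trimmed-mean bootstrap statistics (Yuen's two-sample and paired tests,
    heteroscedastic trimmed-means one-way ANOVA), a repeated cross-validated
    k-nearest-neighbors phenotype classifier with a t-SNE decision map, and a
    synthetic-data module that generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    Rtsne,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
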