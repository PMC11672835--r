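Package: dyadsync
Title: Dyadic Human-Canine Psychophysiological Synchrony Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for canine-assisted interaction (CAI) sessions
    in which a human and a dog each wear synchronized physiological sensors
    (ECG, tri-axial accelerometer, electrodermal activity, skin temperature).
    Signals are reduced onto a shared 10-second epoch grid as per-epoch
    averages (ME) and 10 Hz rolling-window series (RE); time-domain heart
    rate variability (SDNN, RMSSD), activity (MAD, IMA) and electrodermal
    metrics are extracted; per-epoch behavior codes and survey scores
    (SAM, PANAS-SF, MDORS) are integrated; and interspecies synchrony is
    quantified with Pearson correlation, dynamic time warping, and an XNOR
    agreement measure on behavior codes. A synthetic dyad simulator with
    known ground truth (coupled interbeat-interval processes, renderable
    ECG, tonic and phasic EDA, activity bouts, coupled Markov behavior
    states, survey effects) supports validation of every stage. Composite
    outputs include a directional subsession heatmap, a combined synchrony
    table, and a multimodal middle-minute correlation matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
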