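Package: atrialpace
Title: Haemodynamic Modelling and Signal Analysis of Accelerated Atrial Pacing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how accelerated atrial pacing and atrioventricular
    (AV) coupling shape left-heart filling pressure. Provides a closed-loop
    lumped-parameter model of the four cardiac chambers and the systemic and
    pulmonary circulations with time-varying chamber activation, a homeostatic
    pressure-flow regulation module that holds cardiac output and mean arterial
    pressure at set-points across pacing settings, and an in-silico pacing
    trial that sweeps pacing rate and PR interval to map the change in mean
    left atrial pressure (mLAP) in virtual heart-failure-with-preserved-
    ejection-fraction (HFpEF) phenotypes with and without atrial myopathy.
    A companion signal pipeline analyses clinical-style multichannel
    recordings (ECG, left atrial pressure, coronary sinus electrogram) from an
    alternating 30-s sinus/paced protocol: filtering, Pan-Tompkins QRS
    detection, pacing-spike detection, protocol segmentation, per-rate mLAP
    and PR-interval extraction, and paired cohort statistics. A synthetic
    recording generator with exact ground truth makes the pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
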