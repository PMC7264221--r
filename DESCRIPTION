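Package: spikepeel
Title: Peeling Spike Inference and Neuronal Recruitment Analysis for
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying epileptiform neuronal
    recruitment in calcium-imaging recordings of neuron-astrocyte
    co-cultures: ROI detection on the time-averaged movie, per-ROI trace
    extraction, percentile/spline baseline correction to percent dF/F,
    boosted-stump classification of neuronal traces, greedy peeling spike
    inference with a single-exponential non-saturating transient model
    (amplitude 1 percent dF/F, decay 3 s), firing-rate and active-neuron
    recruitment metrics, and two-factor ANOVA with Bonferroni post hoc
    comparisons.  Includes a seeded synthetic-data generator (Poisson
    spike trains, rendered traces and movies, artifact traces, group
    designs) emulating a basal versus 4-aminopyridine experiment, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
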