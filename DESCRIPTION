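Package: vogstage
Title: Oculomotor Parameter Extraction and Two-Stage Staging from
    Video-Oculography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and analysis of 220 Hz
    video-oculography recordings across five stimulus paradigms
    (sinusoidal smooth pursuit, horizontal and vertical visually guided
    reactive saccades, delayed saccades with an acoustic go cue,
    anti-saccades, and rapid alternating voluntary gaze shifts).
    Extracts a fourteen-parameter oculomotor profile per subject
    (pursuit gain and accumulated saccade sum, saccade gains, latencies
    and main-sequence peak velocities, saccadic intrusion rate,
    delayed- and anti-saccade error rates, voluntary gaze-shift
    counts), classifies each parameter against control-derived 1.5 IQR
    Tukey fences, assigns a two-stage oculomotor staging (stage 0 /
    stage 1 executive / stage 2 executive plus brainstem, plus a
    non-conforming category), and runs the cohort-level nonparametric
    statistics (Mann-Whitney, Kruskal-Wallis with post hoc tests,
    Spearman correlations with Holm family-wise error correction). A
    seeded synthetic-recording generator provides ground truth for
    every stage of the pipeline.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
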