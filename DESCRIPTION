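Package: bgloop
Title: Rate Model of the Cortico-Basal Ganglia-Thalamo-Cortical Loop in
    Health and Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a two-channel firing-rate model of the cortico-basal
    ganglia-thalamo-cortical loop performing a two-choice instrumental
    conditioning task with mid-session reversal. Corticostriatal synapses
    are updated by a dopamine reward-prediction-error signal and direct
    prefrontal-to-premotor connections by Hebbian plasticity, so the
    locus of a learned choice migrates from the basal ganglia to cortex
    over training. Ships calibrated healthy, mild Parkinsonian and
    Grade 2 Huntington's disease parameterizations, an in-silico ablation
    of basal-ganglia output (GPi lesion / deep-brain-stimulation
    analogue), session and cohort runners, and post-hoc analyses:
    within-trial oscillation detection, exploration-phase detection and
    a cortical-takeover probe. Results are returned as tibbles for use
    with tidyverse workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
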