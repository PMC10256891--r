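Package: jitaitrial
Title: Geofence-Triggered Just-in-Time Adaptive Intervention Engine and
    Smoking-Cessation Trial Simulator
Version: 0.1.0
Authors@R:
    person("Quit Support", "Engineering", email = "dev@example.org",
           role = c("aut", "cre"))
Description: A deterministic decision engine for a location-aware
    just-in-time adaptive intervention (JITAI) for smoking cessation:
    smoking locations are learned from self-reported smoking events,
    geofences are built around repeatedly reported places, and support
    messages are triggered by dwell time, time of day, reporting
    frequency, and a maintenance-phase decay schedule.  The package also
    provides an agent-based simulator of a two-arm feasibility trial
    (movement, lapse/relapse hazards, app engagement, follow-up and
    biochemical-validation missingness) and the trial statistics needed
    to analyse it: Russell-standard abstinence derivation, Wald odds
    ratios, Newcombe hybrid score intervals for risk differences,
    proportion intervals, Pearson chi-square, a normal-approximation
    Bayesian odds-ratio exceedance probability, and logistic regression
    by iteratively reweighted least squares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
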