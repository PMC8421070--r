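Package: reachplan
Title: Models of Reach Planning Under Goal Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for dissociating motor averaging
    from performance optimization in goal-uncertain ('go-before-you-know')
    reaching experiments. Provides a trial-by-trial state-space learner with
    direction-local motor primitives for multi-force-field adaptation
    studies, error-clamp force-profile analysis (adaptation coefficients,
    cue-aligned normalized profiles, feedback-response detection, and a
    prediction index locating observed behavior between model predictions),
    Gaussian generalization fitting with convolution-based prediction
    refinement, safety-margin models of obstacle avoidance with constrained
    weight fitting and cross-experiment validation, and individuation models
    that decompose inter-participant differences via partial R-squared.
    Includes seeded synthetic-cohort generators for both experiment
    families.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
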