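Package: flyconform
Title: Quantifying Behavioral Conformity in Fly Groups from Arena Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory-analysis pipeline for quantifying social conformity in
    groups of walking flies recorded in a circular arena. Computes each
    individual's visual cue (the summed speed of forward-sector neighbors
    weighted by apparent angular body size), segments speed series into
    walking and stationary states with walk/stop/walking/stay event labels,
    estimates individual sensitivity to the visual cue by lagged linear
    regression, and derives species-level and group-level conformity indices
    from single- versus mixed-species groups. Ships an agent-based arena
    simulator with known ground-truth coupling parameters so the full
    pipeline is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
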