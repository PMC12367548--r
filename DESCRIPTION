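Package: snrreach
Title: Event-Aligned Spike-Train Analysis of Basal Ganglia Output During
    Forelimb Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for extracellular recordings of tonically
    active basal ganglia output (SNr) neurons during skilled forelimb
    behaviour. Detects and segments reach, retraction and food-handling
    events from markerless hand tracking; computes peri-event firing rates
    with a concatenated z-scoring convention; tests per-neuron task-window
    modulation against a permutation null of duration-matched random
    windows; compares trial types with a trial-resampling divergence test;
    screens paired recordings for putative monosynaptic inhibition via
    hollow-Gaussian cross-correlogram deficits with Poisson significance;
    locates pre-movement modulation onsets by sliding-window rank tests;
    and quantifies optogenetic perturbation effects in a cued lever task.
    Includes a fully seeded synthetic-session generator (inhomogeneous
    renewal spike trains, minimum-jerk reach kinematics, coupled pairs,
    opto sessions) with ground truth, so every stage is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
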