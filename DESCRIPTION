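Package: smrsim
Title: Closed-Loop Sensorimotor-Rhythm EEG Brain-Computer Interface Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates closed-loop sensorimotor-rhythm (SMR) motor imagery
    EEG brain-computer interface (BCI) experiments. Intention velocity input
    (scripted controllers or logged pointing-device samples) is encoded into
    source-level alpha-band amplitude modulation via configurable sigmoid
    encoding models (classic, centered, or subject-fitted perturbed
    variants), projected to scalp electrodes through a lead field (loaded
    from file or computed with a built-in analytic multi-shell spherical
    head model), and decoded online with the standard SMR chain: FIR
    preprocessing, small Laplacian at C3/C4, Burg autoregressive alpha-band
    power, rolling Z-score normalization, and velocity-capped cursor
    control. Includes center-out task paradigms (1D left/right and 2D
    left/right/up/down), run and session orchestration with block-randomized
    parameter sweeps, performance metrics (percent trials correct, decision
    time, integrated distance to target, trajectory and covariance
    measures), and trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
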