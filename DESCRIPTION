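Package: reachadapt
Title: State-Space Models of Sensorimotor Learning from Prediction and
    Performance Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying trial-by-trial sensorimotor learning in
    centre-out reaching tasks with error-clamped cursor feedback and
    target jumps. Implements competing state-space models of learning
    from sensory prediction errors (SPE) and task performance errors
    (TPE) -- an SPE-only learner, an Independent Error model with
    additive SPE- and TPE-driven processes, and an Interaction model in
    which TPEs gain-modulate SPE-driven learning -- together with the
    sequential box-constrained least-squares protocols used to fit them
    to cycle-averaged hand deviations, participant-resampling bootstrap
    confidence intervals, a kinematic preprocessing pipeline (zero-phase
    Butterworth filtering, velocity-based movement onset and reaction
    time, hand deviation at peak velocity, exclusion rules, baseline
    correction, cycle and phase summaries), and a synthetic cohort
    generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
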