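Package: irilearn
Title: Inter-Reward-Interval Scaling of Cue-Reward Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how the duration between rewards controls the
    rate of Pavlovian cue-reward learning. Generates trace-conditioning event
    schedules over a wide range of intertrial intervals, synthesizes lick
    trains and two-channel fiber-photometry traces with known ground truth,
    detects the trial at which conditioned responding (or a dopamine cue
    response) emerges from cumulative-sum learning curves, quantifies
    dopamine transients from isosbestic-corrected dF/F, simulates three
    candidate learning models (microstimulus temporal-difference learning,
    SOP, and the retrospective-contingency model ANCCR with an
    IRI-proportional learning rate), and compares models against observed
    trials-to-learn via log-residual sums of squares, AIC, and relative model
    weights, including the log-log regression of trials-to-learn on the
    inter-reward interval.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
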