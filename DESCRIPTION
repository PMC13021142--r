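Package: vagusloop
Title: Closed-Loop Bimodal Vagus Nerve Neuromodulation Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation bench for closed-loop heart-rate regulation by bimodal
    vagus nerve neuromodulation, in which a single virtual electrode either
    stimulates (1-30 Hz, lowering heart rate) or applies 10 kHz kilohertz-frequency
    alternating current (KHFAC) conduction block (raising heart rate). Provides a
    Mamdani-style fuzzy logic controller with singleton outputs, the calibration
    procedure mapping the controller output coefficient to stimulation frequency or
    block amplitude, a synthetic first-order cardiac-vagal plant with a population
    model of animal-to-animal variability, rolling-window R-R interval heart-rate
    estimation, the full perturbation-ramp trial protocol with per-trial
    normalization, and trial performance metrics including the
    Slow/Oscillations/Stable categorization and pairwise rank-sum gain comparisons.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
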