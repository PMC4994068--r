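Package: olfcontrast
Title: Temporal Contrast Analysis of Olfactory Sensory Neuron Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies temporal contrast enhancement in olfactory sensory
    neuron recordings and odor-driven behavior. Provides fluorescence-trace
    preprocessing (ROI averaging, double-exponential photobleaching correction,
    iterated box-car smoothing, percent dF/F), sharpness and decay-time
    statistics for odor responses, extracellular spike detection, amplitude
    sorting and rate estimation, Kalman-filter multi-animal tracking with
    odor-arena kinematics (distance to port, displacement since odor onset,
    binned distance timecourses, postpulse radial velocities), and a seeded
    synthetic-data generator that emulates voltage/calcium imaging traces,
    sensillum recordings, photoionization-detector pulse waveforms and fly
    trajectories so the whole analysis chain is testable without raw
    recordings.
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
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
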