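Package: tremorfb
Title: Sensory-Feedback Force-Tremor Experiment Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a closed-loop sensory-feedback force-tremor
    experiment in essential tremor. Provides the experimental protocol
    (maximum-force calibration, 15 percent target force, visual position and
    auditory pitch feedback mappings under low and high gain, a 12-trial
    schedule), a synthetic-cohort generator emitting timestamped force, pupil
    and event-marker streams, the force processing chain (normalisation,
    zero-phase fifth-order Butterworth 0.1-12 Hz band-pass in second-order
    sections, Welch power spectral density, 4-12 Hz tremor and 0-3 Hz
    voluntary band power, mean force and RMSE), the pupillometry chain (blink
    detection from confidence and gaze acceleration, Gaussian-kernel FFT
    convolution gap interpolation, subtractive baseline correction), and the
    statistical layer (gain contrasts, gated parametric and non-parametric
    tests, trial-level ANOVA, partial correlation, and sequential-design
    power simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
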