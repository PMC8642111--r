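Package: avdegrade
Title: Audiovisual Sensory Degradation Simulation and Gaze Analysis for
    Emotion Recognition Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying audiovisual emotion recognition under
    simulated sensory loss. Simulates moderate sensorineural hearing
    impairment on audio recordings (broadened auditory-filter envelope
    imposition, threshold elevation and loudness recruitment, RMS
    equalization), renders a gaze-contingent relative central scotoma on
    video frames (soft-edged irregular mask over a Gaussian low-pass
    blur), builds the balanced eight-condition experiment schedule,
    computes bias-corrected recognition accuracy (unbiased hit-rates with
    the arcsine transform), filters and scores eye-tracking data against
    dynamic areas of interest, and selects linear mixed-effects models by
    AIC with type-III Wald tests and corrected post-hoc contrasts. A
    synthetic-data module generates speech-like audio, face and hand
    track points, fixation-saccade-blink gaze streams, and
    confusion-structured responses with known ground truth so the whole
    pipeline can be exercised and validated without licensed stimuli.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    lme4,
    car,
    emmeans,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
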