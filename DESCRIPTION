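Package: lumbargait
Title: Gait Events and Spatiotemporal Metrics from Lumbar Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates initial- and final-contact events and spatiotemporal
    gait metrics (step/stride times, step length, gait speed, cadence) from a
    single lumbar-worn tri-axial accelerometer during walking bouts. The
    adaptive detector identifies the vertical and anterior-posterior axes,
    estimates the bout mean step frequency from wavelet power autocovariance,
    locates foot contacts with step-frequency-tuned Gaussian first-derivative
    wavelet transforms of the anterior-posterior signal, applies dynamic
    physiological quality-control thresholds, and converts center-of-mass
    height excursions to step length with one- and two-phase inverted
    pendulum models. A legacy vertical-axis detector with static thresholds
    is included as a comparator, together with a kinematic gait-signal
    simulator with exact ground truth and evaluation tools (event matching,
    F1, mean absolute error, ICC(2,1)).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
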