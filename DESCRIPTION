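Package: entrainalyze
Title: Entrainment, Timing-Decoder and Latency-Variation Analysis of
    Spike Trains in an Oddball Detection Task
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-neuron spike trains recorded while
    subjects detect the omission or deviation of isochronous visual stimuli.
    Provides a validated session container (trial events, spike timestamps,
    eye traces), Gaussian-kernel spike-density estimation and firing
    modulation metrics, neuron classification and inter-stimulus-interval
    duration tuning, a threshold-crossing decoder of next-stimulus timing
    with neuron-resampling bootstrap, millisecond-wise ANOVA localization of
    trial-by-trial saccade-latency covariation, saccade detection from eye
    velocity, and microstimulation effect statistics. A fully seeded
    synthetic generator (task-structured trials, inhomogeneous Poisson
    spikes, eye traces) makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
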