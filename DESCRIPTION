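Package: spikepharm
Title: Single-Unit Drug-Response Analysis for Extracellular Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for pharmaco-electrophysiology of
    extracellular single-unit recordings. Simulates seeded spike trains and
    voltage traces with a baseline / post-injection session structure,
    detects spikes by threshold crossing with spike-height window
    discrimination, bins discharges into peri-stimulus time histograms,
    classifies per-neuron drug responses against baseline variability
    (k standard deviations sustained over consecutive bins), measures onset
    latency and percent change, and performs group-level paired pre/post
    inference with response-class counts and mean +/- SEM time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
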