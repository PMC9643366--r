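Package: vnstim
Title: Vestibular Nucleus Spike-Train Regularity, GVS Dosimetry and
    Receptor Dose-Response Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for vestibular-nucleus electrophysiology in a
    6-OHDA Parkinson's-disease rat model under galvanic vestibular stimulation
    (GVS). Simulates gamma-renewal spike trains with sinusoidal or adapting
    step rate modulation, computes inter-spike intervals, instantaneous firing
    rates and the rate-normalized coefficient of variation (CV*) used to
    classify discharge regularity, characterizes tonic versus phasic GVS
    responses, computes delivered electrical charge from pulse-train
    protocols, and runs group-level two-sample t statistics on glutamate
    receptor densities, including the NMDA dose-response across stimulation
    charges. A synthetic-data generator stands in for recordings and
    histology so the whole pipeline is reproducible from a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
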