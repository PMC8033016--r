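Package: egmprint
Title: Signal Fingerprinting of Unipolar Atrial Electrograms
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multichannel unipolar atrial electrograms recorded
    during sinus rhythm with high-resolution epicardial electrode arrays.
    Detects negative deflections, annotates local activation times, classifies
    potentials as single, short/long double or fractionated, computes R/S
    ratios, peak-to-peak voltages and fractionation durations, detects
    conduction block between adjacent electrodes on the grid, and aggregates
    everything into a per-region quantified "signal fingerprint" with
    Spearman correlation statistics. A 2D wavefront/electrogram forward
    simulator provides ground truth so the whole pipeline is verifiable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'activation.R'
    'classification.R'
    'cli.R'
    'deflections.R'
    'egmprint-package.R'
    'fingerprint.R'
    'io.R'
    'simulate.R'
    'stats.R'
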