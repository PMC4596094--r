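Package: prebotc
Title: Two-Compartment Model of Coupled Eupnea and Sigh Rhythms in the
    Pre-Botzinger Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of the embryonic pre-Botzinger
    complex respiratory network as two coupled population compartments: a
    fast eupnea oscillator driven by persistent-sodium-current kinetics and
    a slow sigh oscillator driven by two-pool (cytosol/endoplasmic
    reticulum) calcium dynamics, connected by an inhibitory synapse from
    eupnea to sigh and a stronger excitatory synapse from sigh to eupnea.
    Provides the full parameterisation of both compartments, adaptive
    stiff integration of the 12-dimensional system via 'deSolve', burst
    detection and amplitude-based rhythm classification, post-sigh apnea
    and burst-shape statistics, and a registry of named in-silico
    experiments (coupling variants, conductance knockdowns, excitability
    sweeps) reproducing the model's characteristic behaviours.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
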