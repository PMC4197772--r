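Package: granulesim
Title: Compartmental Models of Olfactory Bulb Granule Cells with Active
    Dendrites and Explicit Dendritic Spines
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds stylized multicompartment models of the three
    morphological classes (type I, II, III) of olfactory bulb granule
    cells, with Hodgkin-Huxley style active dendrites, explicit
    two-compartment dendritic spines carrying AMPA and NMDA receptor
    synapses with voltage-dependent magnesium block, a sub-membrane
    calcium shell fed by the fractional NMDA calcium current, and an
    extended Goldman-Hodgkin-Katz reversal potential for the NMDA
    channel. A Crank-Nicolson implicit cable solver (Hines elimination
    on the dendritic tree, implemented in C++) integrates voltages,
    gates, synapses and shell calcium. Experiment drivers reproduce
    spine-count thresholds for action potential generation in different
    dendritic regions, determination of the action potential initiation
    site (dendrite versus soma), tangential-plane stimulation with and
    without a hyperpolarizing somatic hold, and magnesium sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
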