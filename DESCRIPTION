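Package: colspike
Title: Spiking Cortical Column Simulation and Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of a laminar cortical column of leaky integrate-and-fire
    neurons with conductance-based AMPA, NMDA (voltage-dependent magnesium block)
    and GABA-A synapses, organised into 17 cell groups (pyramidal, PV, SST and VIP
    interneurons across layers 1, 2/3, 4, 5 and 6). Networks are built from
    group-level connection-probability, synaptic-strength and Gaussian-width
    matrices with size-invariant weight scaling and a disk-uniform probability
    correction. Includes Poisson background drive, feedforward/feedback/combined
    DC stimulation protocols, single-group perturbations, and the analysis suite
    for perturbation response matrices: firing rates, inter-spike-interval
    irregularity, voltage synchrony, power spectra, percent-change matrices,
    threshold categorisation, comparison matrices and Frobenius distances. A
    seeded synthetic-connectivity generator makes the package fully testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
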