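Package: lanmm
Title: Laminar Neural Mass Modeling of Serotonergic Neuromodulation in
    Cortical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a laminar neural mass model
    (LaNMM) of the cortical column, in which a Jansen-Rit circuit generating
    alpha-band activity in layer-5 pyramidal cells is coupled to a
    pyramidal-interneuron-gamma (PING) circuit generating gamma-band activity
    in supragranular layers.  The package integrates single columns and
    connectome-coupled whole-brain networks of columns, models serotonin-2A
    receptor agonism (psychedelics) as a receptor-density-weighted increase of
    the glutamatergic synaptic gain onto layer-5 pyramidal populations, and
    provides the downstream observables: gain sweeps of band power, balloon-
    model BOLD and functional connectivity with grid-search personalization,
    leadfield projection to scalp EEG, band-power statistics, and
    complexity/entropy metrics (Lempel-Ziv-Welch rho0, entropy rate, spectral
    entropy).  A synthetic-data module generates connectomes, receptor maps,
    leadfields and target functional connectivity so the full pipeline runs
    without neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
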