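Package: glioscale
Title: Multiscale, Multi-Resolution Agent-Based Glioblastoma Growth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates glioblastoma (GBM) expansion as a hybrid
    discrete-continuum, multiscale agent-based model. An intracellular
    EGFR/PLCgamma signalling network (11 species, mass-action and
    Michaelis-Menten kinetics) drives each cell's migration-proliferation
    phenotype decision; cells act on a dual-resolution lattice whose
    low-resolution clusters are classified as heterogeneous or homogeneous
    so that full intracellular computation is spent only on the tumour rim;
    and a chemoattractant (TGFalpha) reaction-diffusion field couples the
    scales, solved by an alternating-direction implicit (ADI) scheme with
    Thomas sweeps and an optional alternating-Schwarz overlapping-tile
    decomposition. An analysis layer produces population curves with
    crossing detection, phenotype-switch molecular profiles, cluster maps,
    high-resolution phenotype maps and single-cell trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
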