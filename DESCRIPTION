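Package: cavsolv
Title: Binding-Cavity Solvation Mapping from Simulation Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the structure and energetics of water in and around protein
    binding cavities from simulation frames. Implements voxel-grid water
    density and energy mapping referenced to neat water, geometric
    hydrogen-bond detection and per-functional-group solvation statistics,
    hydration-site analysis with donor/acceptor classification,
    ligand-proximity subvolume integration with block-averaged errors, and
    rigid-versus-flexible comparison reports. A Metropolis Monte Carlo
    generator supplies synthetic water/solute ensembles with known
    statistical structure so every analysis stage can be validated at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
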