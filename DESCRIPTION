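Package: wrinklesim
Title: Agent-Based Mechanics of Cell-Death-Triggered Biofilm Wrinkling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Off-lattice agent-based simulation of bacterial biofilm
    mechanics in which localized cell death at the colony-substratum
    interface triggers wrinkle formation. Each agent is a sphere
    representing one cell plus its attached extracellular polymeric
    substance (EPS); agents interact through a hysteretic elastic bond
    network and an elastic agar-substratum force, and move by overdamped
    Brownian dynamics integrated with the Euler-Maruyama scheme. Includes
    generators for compressed random packings at a target volumetric
    density, cell-death-pattern ablation (rectangular or image-defined,
    abrupt or gradual), per-agent virial stress tensors, voxel height-map
    morphometrics (colony height, center-to-border height ratio, wrinkle
    area, displacement and convergence fields), an in-silico uniaxial
    compression rheometer with stiffness estimation, seeded parameter
    sweeps, YAML run configuration, snapshot serialization (CSV and
    extended XYZ) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    yaml,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
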