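Package: cgfork
Title: Coarse-Grained Replication-Fork Simulation and Histone-Recycling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds residue-level coarse-grained models of replisome proteins and
    three-site-per-nucleotide forked DNA, evaluates structure-based (Go) contact
    potentials with Debye-Huckel electrostatics and excluded volume, propagates
    them with Langevin dynamics and temperature replica exchange, estimates
    protein-protein binding free energies from native-contact (Q-score) bound-state
    populations, and provides the trajectory analytics used to characterise histone
    H3/H4 recycling at a replication fork: contact time series, association
    survival, ring-based coordinate frames, elevation/azimuth angles, spatial
    densities with iso-surfaces, recycling-pathway classification, and
    fork-junction destination distances. A synthetic replisome generator produces
    desk-scale systems and scripted, ground-truth-labelled trajectories so every
    analysis stage is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
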