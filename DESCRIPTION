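Package: alloscan
Title: Per-Residue Prediction of Allosteric Site-Forming Residues from
    Protein Structures
Version: 0.1.0
Authors@R:
    person("alloscan", "developers", email = "alloscan@example.org",
           role = c("aut", "cre"))
Description: Labels allosteric site-forming residues (AFRs) in holo/apo
    structure pairs through loss of accessible surface area (LASA) and a
    5 Angstrom modulator-distance rule, computes a panel of per-residue
    nanoenvironment descriptors (relative accessibility, void "sponge"
    fraction, distance to the chain centre of geometry, neighbourhood
    hydrophobicity, Coulomb electrostatic potential, backbone hydrogen-bond
    energies, and contact-graph eccentricity and betweenness), reduces the
    panel by Pearson-correlation pruning and two-sample Kolmogorov-Smirnov
    filtering, trains one class-weighted gradient-boosted classifier per
    amino-acid residue type, and evaluates predictions with
    Distance-Center-Center (DCC) site metrics and standard residue-level
    classification metrics.  Ships a synthetic helix/modulator generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
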