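Package: cgimm
Title: Coarse-Grained Modelling of Membrane Proteins in Implicit
    Water-Membrane Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A residue-based coarse-grained protein model combined with a
    Gaussian solvent-exclusion implicit solvation term and an implicit
    membrane of the IMM1 family (z-dependent environment switching and a
    membrane-attenuated distance-dependent dielectric). Provides MARTINI-style
    mapping of all-atom PDB structures to beads, analytic energies and forces,
    Langevin dynamics, secondary-structure geometry metrics and a trajectory
    fitness score, and a generational genetic algorithm that optimizes the
    solvation parameter table against a training set. Includes generators for
    synthetic peptide fixtures (ideal helices, strands, hairpins,
    transmembrane bundles) with closed-form reference geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
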