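Package: LatticePartition
Title: Lattice-Energy Partitioning for Crystals of Flexible Molecules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions lattice energies of molecular crystals of flexible
    compounds into intermolecular and intramolecular components, the latter
    further resolved into conformational adjustment (strain) and global-change
    terms, each anchored to an explicit gas-phase reference state. Includes a
    periodic classical force-field backend with local geometry optimizers and a
    torsion-grid conformer search so the full partition pipeline runs on toy
    flexible-molecule crystals, polymorph-stability benchmarking against
    experimental enthalpy differences (mean absolute deviations across model
    grids), the intra-to-intermolecular energy-ratio analysis with its empirical
    40 percent upper envelope, a kink-site crystal-growth stabilization score,
    and synthetic-data generators for energy tables, benchmark sets and toy
    polymorph pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction, Software
RoxygenNote: 7.3.3
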