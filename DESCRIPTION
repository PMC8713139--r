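Package: redoxbond
Title: Redox Potentials and Classification of Protein Disulfide Bonds from
    Non-Equilibrium Alchemical Work Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates disulfide-bond reduction free energies from
    forward/backward non-equilibrium alchemical work values using the
    Crooks Gaussian Intersection and Bennett acceptance ratio estimators,
    with bootstrap uncertainties and distribution-overlap diagnostics.
    Converts free energies to reduction potentials via the two-electron
    Nernst relation, applies a linear calibration to the experimental
    scale, and classifies each bond as functional or structural by its
    corrected potential. Also builds dual-state hybrid cysteine/cystine
    residue topologies for alchemical transformations, detects disulfide
    bonds in PDB coordinates, and generates Crooks-consistent synthetic
    work data so the whole pipeline is testable without molecular
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
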