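Package: xtalmd
Title: Build Hydrated Protein Crystal Unit Cells for Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the construction of fully hydrated crystallographic
    unit cells for molecular dynamics simulations. Reads PDBx/mmCIF
    structures with cell and space-group metadata, cleans the asymmetric
    unit (altloc selection, gap detection, clash reporting, rule-based
    protonation), expands it to the full unit cell via Seitz-matrix
    symmetry operations transformed to Cartesian space, plans solvent and
    neutralizing ions over a grid of van-der-Waals overlap scale factors,
    emits a complete GROMACS run recipe, and verifies the solvent count by
    comparing mean simulated box volumes against the experimental
    unit-cell volume with an iterative refinement proposal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
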