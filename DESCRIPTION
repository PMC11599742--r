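Package: annulipid
Title: Annular Lipid Shell Analysis for Membrane-Protein Crystal Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the crystallographic analysis of annular (first-shell)
    lipids around membrane proteins, developed for microbial rhodopsins.
    Classifies the three-letter chemical-component codes used to model lipid
    fragments, partitions PDB/mmCIF structures into protein, retinal, lipid
    and solvent sets, superposes structures on backbone and retinal atoms
    (Kabsch and quaternion solvers), assigns a membrane coordinate frame with
    hydrophobic-hydrophilic boundaries, extracts the 5 Angstrom annular shell,
    computes lipid-to-protein-surface nearest-atom distance statistics,
    profiles lipid and noble-gas atom depths across the bilayer with mode
    detection, reports per-protomer lipid censuses, and generates fully
    specified synthetic membrane-protein scenes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
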