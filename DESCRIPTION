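Package: pmhc2model
Title: Template-Based Modelling of Peptide-MHC Class II Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Homology-driven, anchor-restrained modelling of peptide-MHC class II
    (pMHC-II) complexes. Provides curated template-set handling (chain
    standardization, peptide-length and DM/CLIP filtering), sequence-identity
    template selection with core-anchored PAM30 peptide alignment, derivation of
    anchor distance restraints from template contacts, a restraint-guided
    conformer engine that builds and ranks peptide ensembles by a transparent
    pseudo-energy, backbone ligand-RMSD evaluation (core, flanking, whole), a
    leave-one-out benchmark harness, and a synthetic pMHC-II fixture generator
    with known ground-truth geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    bio3d,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
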