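Package: rwpot
Title: Random-Walk Reference-State Statistical Potentials for Protein Model
    Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and applies knowledge-based statistical potentials for
    scoring protein structural models. Implements a pair-wise
    distance-dependent atomic potential whose reference state is a
    freely-jointed (random-walk) chain, a side-chain orientation-dependent
    packing term over binned relative orientations of residue vector pairs,
    and a hybrid score combining both. Includes a residue-specific heavy-atom
    typing scheme (158 types), training from PDB structure libraries,
    decoy-set evaluation (native recognition, Z-scores, top-k model
    selection, energy-quality correlations), Kabsch superposition RMSD, and
    seeded synthetic structure and decoy generators for desk-scale testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
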