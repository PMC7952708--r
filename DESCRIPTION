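Package: fretpairs
Title: Residue-Pair Selection for smFRET and EPR Labeling from
    Conformational Distance Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens all residue pairs of a protein observed in two (or
    more) conformations for suitability as fluorophore or spin-label
    attachment sites. Builds side-chain center-of-mass distance maps per
    conformation, signed difference maps between conformations, and
    per-residue relative solvent accessibility (built-in Shrake-Rupley
    engine or classic DSSP files), then filters pairs by a distance
    window, a minimum absolute distance shift, and a relative-accessibility
    cut-off. Results export as tidy tables, CSV matrices, and PyMOL viewer
    scripts; a synthetic two-conformation fixture generator with
    analytically known geometry supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
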