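Package: affimask
Title: Triage and Analysis Toolkit for Masked Miniprotein Binder Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational support for protease- and
    photo-activatable ("masked") de novo miniprotein binders. Reads predicted
    complex structures (PDB/mmCIF) together with per-residue pLDDT and
    pairwise PAE confidence data, computes the interface-contact, mask
    coverage, orientation and superposition metrics used to filter candidate
    mask designs, ranks survivors and picks a sequence-diverse shortlist.
    Also assembles full cleavable constructs (His-tag, binder, GS linker,
    MMP-cleavable motif, mask), simulates proteolytic and photolytic
    cleavage with average/monoisotopic mass bookkeeping, projects helical
    wheels and hydrophobic moments, simulates and globally fits 1:1
    biolayer-interferometry sensorgrams, fits four-parameter logistic
    dose-response curves, and classifies masking efficiency by IC50
    fold-shift. A synthetic fixture generator builds helix-bundle design
    bundles with planted ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
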