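Package: oligotriage
Title: Immunohistochemistry-Based Triage of Adult Diffuse Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tested re-implementation of a computational chain for triaging
    adult diffuse gliomas by immunohistochemistry: automated Otsu-based
    H3K27me3 intensity scoring of stained tissue fields, cell-fraction
    nuclear scoring with the 25%/75% rule, FISH-based 1p/19q codeletion
    calling, cohort contingency statistics with hierarchical clustering of
    intensity scores, and a recursive-partitioning classifier over three
    binary immunostains (H3K27me3, ATRX, IDH1-R132H) that predicts
    IDH-mutant 1p/19q-codeleted oligodendroglioma. Ships a seeded
    brightfield field-image simulator with per-nucleus ground truth, a
    seeded FISH signal-count simulator, and a 145-case cohort fixture
    reconstructed from published summary counts, so the whole pipeline is
    exercisable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    jsonlite,
    withr,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
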