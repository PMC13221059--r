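Package: sachwear
Title: Grid-Based Plantar Wear Scoring and Rater Reliability for Prosthetic Feet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying mechanical wear on the plantar surface of
    SACH (solid ankle cushion heel) prosthetic feet with an ordinal visual
    scoring rubric applied through a 20x10 grid overlay. Implements the
    original 0-9 and minimalist 0-5 wear scales and the many-to-one collapse
    between them, grid fitting to foot outlines with per-cell coverage and the
    50%-fill NA rule, tie-corrected Kendall's coefficient of concordance
    computed per cell (across feet) and per foot (across cells), agreement
    categorization, intraobserver cell-level agreement counting, a seeded
    simulator of synthetic feet, wear fields and noisy ordinal raters, long
    format CSV score I/O, heatmap export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    withr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
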