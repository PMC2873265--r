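Package: foldexpansion
Title: Fold Ancestry and Expansion Analysis of Protein Functional Categories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the evolutionary expansion of protein fold
    architectures across functional categories. Computes per-fold ancestry
    values from a rooted fold phylogeny by node counting, builds nonredundant
    per-category fold censuses from protein-to-fold mapping tables, derives
    cumulative fold-expansion curves with threshold and area-under-curve
    summaries, locates evolutionary era boundaries (RNA-protein world, era of
    the Last Universal Common Ancestor, modern era) from marker folds, and
    reports the functional coverage of the most ancestral folds. Includes a
    synthetic-data generator for fold phylogenies, censuses, and marker sets
    so the whole pipeline can be exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
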