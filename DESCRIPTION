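Package: glycoshift
Title: Structure Elucidation of Di- and Trisaccharides from Unassigned 13C-NMR Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Spectra-structure relationship modelling for pyranosyl di- and
    trisaccharides. Encodes an unassigned, ascending-sorted list of 13C
    chemical shifts as a fixed-length 23-descriptor vector and predicts nine
    structural attributes (three anomeric configurations, two glycosidic
    linkage types, three residue identities, and the chain type) with random
    forests, CART classification trees, and a counterpropagation neural
    network built on a toroidal Kohonen self-organizing map. Includes an
    additive increment-model simulator of 13C spectra for glucose, galactose,
    mannose, rhamnose and fucose oligomers, a SOM-assisted diversity 3:1
    train/test split, out-of-bag and 10-fold cross-validated evaluation with
    per-class sensitivity and precision-style specificity, and descriptor
    importance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    Rcpp,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
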