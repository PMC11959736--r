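Package: rfstab
Title: Stability-Guided Choice of the Number of Trees in Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Random forests are non-deterministic: repeated runs on identical
    data give different predictions, variable importances, and therefore
    different selection decisions. rfstab quantifies this run-to-run stability
    as a function of the number of trees (intraclass correlation ICC(1,1) for
    continuous outputs, Fleiss' kappa for categorical outputs and for
    top-alpha selection decisions), models the relationship with a
    two-parameter logistic curve fitted by Levenberg-Marquardt, and recommends
    the smallest tree count beyond which additional trees give negligible
    stability gain. Designed for small-n-large-p settings such as genomic
    selection with SNP genotype predictors, and ships a synthetic
    genotype/phenotype simulator so every pathway can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    minpack.lm,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
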