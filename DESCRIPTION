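Package: tetraseg
Title: Tetrasomic Segregation Analysis with Double Reduction and
    Gametophytic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genetic analysis of selfed autotetraploid (and diploid)
    plants segregating a gametophytically acting allele. Computes exact
    gamete-class frequencies under tetrasomic inheritance with a
    configurable double-reduction coefficient, applies sex-specific
    gametophytic selection (female abortion, reduced male transmission
    efficiency), derives expected seed-set, progeny-marker and
    female-gametophyte phenotype ratios for candidate dosage/dominance
    models, and selects the best-fitting model by Pearson chi-square
    goodness of fit. Includes a seeded forward simulator of selfing
    progeny for power and parameter-recovery studies. All probabilities
    are carried as exact rational numbers; floating point enters only at
    reporting and test statistics.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vctrs
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
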