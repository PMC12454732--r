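Package: vkdbe
Title: MS1-Level Metabolite Class Annotation from Van Krevelen Ratios and Double Bond Equivalents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Class-level (MSI Level 3) annotation of specialized plant
    metabolites from high-resolution MS1 data alone. Computes
    formula-derived descriptors (H/C and O/C atomic ratios, double bond
    equivalents, modified aromaticity index, carbon count) from molecular
    formulas or accurate masses, enumerates candidate elemental
    compositions for observed m/z values under a ppm tolerance, and
    assigns phenolic, alkaloid and isoprenoid compound classes using
    curated descriptor range windows with DBE-based overlap resolution.
    Ships Van Krevelen, DBE-distribution, range-bar, boxplot and 3D
    diagnostic graphics, a class-consistent synthetic-formula generator,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    lattice,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
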