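Package: pedoconverge
Title: Convergence Analysis of Urban Soil Property Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies whether urbanization homogenizes soils at depth.
    Resolves horizon-level descriptions of paired urban and pre-urban
    reference pedons (USDA texture class, Munsell color value, optional
    measured total carbon) to 1-cm depth slices over 0-150 cm, converts
    texture classes to geometric mean particle diameter and color to total
    carbon via a log-linear pedotransfer function, summarizes vertical
    structure with the Index of Profile Anisotropy, and quantifies
    convergence with per-depth log-log regressions of the urban:reference
    ratio on the reference level, extracting the point of convergence at
    each depth and fitting universal urban profile models (quartic particle
    size, exponential carbon). Includes a synthetic paired-pedon generator
    with known convergence targets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
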