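Package: layerquant
Title: Per-Layer Marker Quantification and Prognostic Statistics for 3-D
    Tissue Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies multi-channel confocal z-stacks of cleared tissue into
    per-layer relative marker intensity profiles (marker pixels over membrane
    pixels), compares two subjects' layer profiles with an exact paired
    sign-flip permutation test using midpoint tie ranks, scans expression
    cutoffs for the value maximising Youden's index with covariate-adjusted
    proportional-hazards fits and Kaplan-Meier comparisons, summarises paired
    tumour/normal immunohistochemistry scores, and filters genes for
    concordant up/down log2 fold changes across two contrasts. Ships a
    synthetic-data module that generates every input class with known ground
    truth so the whole pipeline is testable end to end.
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
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
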