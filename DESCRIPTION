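Package: adipoquant
Title: Automated Quantification of Adipogenic Differentiation from Multichannel Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify adipogenic differentiation of mesenchymal stem
    cells from multichannel fluorescence and brightfield microscopy. Provides
    nuclei-seeded watershed and lipid-channel instance segmentation of cells,
    lipid-droplet segmentation by green-channel thresholding, per-pixel
    Oil Red O positivity (R/(G+B) > 1), GFP auto-contrast normalization and
    per-cell intensity maxima, droplet-containing cell selection and
    differentiated-cell fractions, GFP/Oil-Red-O double-positive gating with
    scatter plots, field-of-view sampling estimators, fold-change arithmetic,
    group statistics (Kruskal-Wallis with Dunn post hoc, two-way ANOVA with
    Tukey HSD, 2^-ddCt relative expression, dye-elution normalization), and a
    ground-truthed synthetic well generator emulating confluent monolayers
    with controllable adipocyte and GFP-transduced fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    withr,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
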