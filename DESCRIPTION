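Package: trichromequant
Title: Quantitative Histomorphometry of Masson's Trichrome-Stained Skin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reproducible histomorphometry protocol for
    brightfield photomicrographs of Masson's trichrome-stained skin:
    Beer-Lambert optical-density conversion, estimation of custom stain
    vectors from regions of interest, two-stain color deconvolution into
    8-bit stain-amount channels, construction of a connective-tissue mask
    (Gaussian blur, iterative-intermeans auto-threshold with black pixels
    ignored, binary closing), per-stain thresholding restricted to the mask,
    and calibrated extraction of area, intensity and distribution-shape
    features (skewness, kurtosis). Includes a normality-gated statistical
    comparison framework (Shapiro-Wilk gate selecting Student's t or
    Mann-Whitney U), paired linear regression, a synthetic trichrome scene
    generator with known ground truth for end-to-end validation, and a
    command-line interface for batch analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
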