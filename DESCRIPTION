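Package: reeftraits
Title: Decomposing Coral Assemblage Trait Change into Intraspecific
    Variation and Species Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trait-based analysis of community change along an environmental
    gradient, built around coral assemblages surveyed by line-intercept
    transect. Computes standardized effect sizes of colony location on traits
    from linear and mixed-effects models, community-weighted means (CWMs)
    under fixed (study-wide) versus local (site-specific) species means,
    sums-of-squares decomposition of assemblage trait variation into
    composition-driven, intraspecific and covariation components,
    amplification and reduction factors for compositional trait shifts, and
    trait-space ordination with species and assemblage shift vectors.
    Includes a synthetic community generator with known ground truth for
    parameter-recovery testing, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
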