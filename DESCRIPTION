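Package: coactive
Title: Network Ensemble Detection and Dendritic Spine Quantification for
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for spontaneous-activity analysis in
    cultured cortical networks imaged with a calcium indicator: background
    subtraction, saturated-cell exclusion, sliding lower-half dF/F baselining,
    fast non-negative spike deconvolution under an AR(1) calcium model,
    binarization of spike probabilities, permutation (shuffle) nulls for
    per-frame co-activity, detection of network ensembles and core ensembles,
    and nonparametric two-group comparisons. Also quantifies dendritic spine
    densities from tabulated spine-trace records under explicit inclusion
    criteria, and ships a synthetic-data generator that plants ground-truth
    co-activation ensembles so every stage can be validated against a known
    answer.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
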