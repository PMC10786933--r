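Package: diagentropy
Title: Entropy Removal and Information-Theoretic Evaluation of Diagnostic Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the diagnostic value of medical tests as the Shannon
    entropy removed from the disease-state distribution by conditioning on the
    test result (the mutual information between test and disease), computed
    from 2x2 confusion counts or from printed sensitivity, specificity and
    predictive values. Also provides classical accuracy metrics (sensitivity,
    specificity, predictive values, Youden's index, diagnostic odds ratio),
    prevalence inversion from predictive values, entropy removed per unit
    cost, an entropy-criterion decision-tree inducer over binary clinical
    features with node and feature importance accounting, a seedable
    generator of synthetic binary patient cohorts from stratified
    decision-algorithm specifications, and batch correlation studies
    comparing entropy removal against classical metrics with Fisher-z
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
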