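Package: loopdiffr
Title: Differential Chromatin Loop Calling for Hi-C and 5C Contact Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical identification of cell type-specific chromatin looping
    interactions across two or three biological conditions. For genome-wide Hi-C
    contact matrices the package fits a negative-binomial model with Knight-Ruiz
    bias vectors, distance-dependent median-of-ratios size factors and a
    distance-dispersion relationship estimated by quantile-adjusted conditional
    maximum likelihood with precision-weighted LOWESS smoothing, then tests each
    pixel with a likelihood-ratio test and controls the false discovery rate over
    loop pixels. For 5C fragment matrices it models the mean-variance relationship
    of normalized counts, simulates null pseudoreplicates, converts counts to
    interaction scores through matrix balancing, local donut/lower-left expected
    models and log-logistic p-values, and classifies differential loops by an
    empirical-FDR threshold sweep. Count simulators with known truth labels, an
    evaluation harness (ROC, FDR control, power, distance strata) and parametric
    benchmark tests (ANOVA, unit-variance normal LRT on z-scores) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
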