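Package: salivanmr
Title: Salivary 1H-NMR Metabolomics with Multilevel PLS and OPLS-DA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of one-dimensional 1H-NMR saliva spectra for
    paired clinical designs: chemical-shift calibration, 0.02 ppm bucketing
    with water-region exclusion, total-area normalization and metabolite
    signal-area integration; multilevel (paired) PLS-DA and OPLS-DA latent
    variable models fitted by NIPALS with orthogonal signal correction;
    Monte Carlo cross-validation, confusion matrices and permutation tests
    on model accuracy; and a nonparametric per-metabolite statistics layer
    (Kruskal-Wallis, paired Wilcoxon, Mann-Whitney) with Benjamini-Hochberg
    false discovery rate control. A synthetic-data generator emulates a
    periodontitis treatment cohort (paired baseline/post-therapy samples
    plus independent healthy controls) over a packaged 31-metabolite
    reference panel, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
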