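Package: normdev
Title: Normative Deviation Modelling and Neuroanatomical Heterogeneity Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-region normative modelling of brain morphometry (cortical
    thickness and subcortical volumes) with transfer adaptation to new
    scanners/sites, individual deviation z-score maps, outlier binarization,
    total outlier counts, within-group Hamming-distance dissimilarity,
    per-region outlier proportions, and a severity-stratified nonparametric
    statistical battery. Includes a multi-site synthetic cohort generator so
    the whole pipeline is testable without access-restricted clinical data,
    readers for FreeSurfer-style stats tables, and a reproducible end-to-end
    pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
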