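Package: cpacor
Title: Control Probe Adjustment and Reduction of Global Correlation for
    Epigenome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for Infinium 450K-style DNA methylation
    arrays in epigenome-wide association studies (EWAS): quality control with
    a calibrated detection P value threshold, stratified quantile
    normalisation of signal intensities, principal-component adjustment for
    technical batch effects estimated from control probes, reference-based
    white blood cell deconvolution, per-marker association testing, and
    permutation-based inflation diagnostics. Includes a synthetic array
    generator that emulates chip batch effects, cell-mixture covariation,
    locally correlated CpG clusters, duplicate designs and spike-in effects,
    so the whole pipeline can be exercised and validated without real array
    data.
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
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    broom,
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
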