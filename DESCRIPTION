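Package: thermoresp
Title: Cross-Species Transcriptomic and Photosynthetic Thermal Stress Response Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing transcriptomic temperature-stress responses
    across plant species that lack a common reference genome. Gene expression
    (TPM) from per-species de novo assemblies is summarized over biological
    process GO terms with a subset-size-controlled boot-strapped median, and
    over orthogroups with member means. Treatment responses are modelled with
    random-intercept linear mixed models (variance partitioning via ICC and
    marginal R2), biome differentiation with fixed-effect linear models on
    species-level log2 fold changes, and associations between expression
    responses and photosystem II thermal tolerance acclimation with linear
    models. Includes segmented-regression extraction of critical temperatures
    (Tcrit, Tmax) from chlorophyll fluorescence temperature ramps, readers for
    RSEM, Trinotate and OrthoFinder outputs, a ground-truth-bearing synthetic
    data generator, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
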