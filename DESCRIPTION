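Package: famprs
Title: Family History and Polygenic Risk Under the Liability-Threshold Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A family-structured liability-threshold simulator and analysis
    pipeline for the systematic comparison of registry-derived family history
    (first-degree, second-degree, and parental cause of death) with polygenic
    risk scores (PRS). Provides pedigree simulation with additive genetic
    transmission, shared family environment and registry-window-censored
    parental death records; kinship-based relationship classification and
    family-history derivation; covariate-adjusted logistic regression with
    cross-adjustment and proportional log-odds attenuation, PRS percentile
    bands, interaction tests with Bonferroni correction; Kaplan-Meier
    cumulative incidence by age 80 stratified by family history and PRS
    group; and observed and theoretical (bivariate normal) concordance of
    high PRS among relative pairs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
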