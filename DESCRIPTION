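Package: dietprs
Title: Joint Dietary and Polygenic Risk Score Analysis of Colorectal Cancer Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how habitual diet and common genetic variation
    jointly shape colorectal cancer (CRC) incidence in a prospective cohort.
    Implements a World Cancer Research Fund (WCRF) dietary adherence score and
    an inverse-variance-weighted dietary score over eleven food groups; curation
    of a CRC susceptibility variant manifest with linkage-disequilibrium proxy
    substitution and three polygenic risk score (PRS) weighting schemes;
    adjusted Cox proportional-hazards models with trend and likelihood-ratio
    interaction tests, joint diet-by-PRS category tables and PRS-stratified
    fits; covariate-adjusted cumulative risk at age 80 on the age timescale
    with delayed entry; excess-risk decompositions and Levin attributable
    fractions. A synthetic cohort generator with hazard-calibrated event times,
    questionnaire-style diet variables and Hardy-Weinberg genotypes makes the
    whole pipeline testable end to end without access to restricted cohort
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
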