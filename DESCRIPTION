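Package: citrusvol
Title: Volatile Biomarker Mining and Rule-Based Identification of Citrus Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy chemometrics pipeline for mining species-discriminating
    volatile compounds from germplasm-by-compound GC-MS content tables
    (ng/g fresh weight) and for classifying citrus germplasms with
    single-compound marker rules. Provides delimited-text readers for
    volatile profiles with species labels, a minimum-detection presence
    filter, per-species presence (Venn) accounting, principal component
    analysis via singular value decomposition, NIPALS partial least
    squares discriminant analysis with variable importance in projection
    (VIP) scores, one-vs-rest marker selection combining a VIP threshold
    with a normality-gated two-group significance test, a four-rule
    presence/threshold classifier for loose-skin mandarin, sweet orange,
    pomelo and lemon, and a seeded log-normal simulator of volatile
    matrices with planted marker compounds for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
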