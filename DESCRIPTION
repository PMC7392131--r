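Package: cartrake
Title: Selection-Bias Characterization and Raking Weights for Loyalty-Card Purchase Cohorts
Version: 0.1.0
Authors@R: person("LoCard", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for characterizing and correcting volunteer selection bias in
    consumer-panel cohorts assembled from retailer loyalty-card data. Provides a
    synthetic cohort generator (biased consent, questionnaire nonresponse,
    zero-inflated right-skewed purchase records), a unit-level raking
    (iterative proportional fitting) weight builder over multiple one- and
    two-way population margins with weight trimming, two-phase handling of
    questionnaire missingness and rescaling, recency-frequency-monetary (RFM)
    loyalty scoring, food-group purchase summarization with weighted quantiles,
    and stratified group comparisons (chi-square, Kruskal-Wallis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
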