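Package: satscreen
Title: Saturation Analysis of Prognostic Gene Discovery in Survival Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Resampling-based saturation analysis of per-gene prognostic
    screening in cancer cohorts. Binary somatic mutation indicators are
    screened gene-by-gene with Kaplan-Meier estimation and the two-group
    log-rank test inside repeated random subsamples drawn at a grid of
    cohort sizes; the growth of the significant-gene count with cohort
    size and with outcome-events number is fitted with a power law, and
    the probability of obtaining at least one significant gene with a
    logistic cumulative distribution function, inverted to minimum
    cohort-size and events requirements. Includes a synthetic cohort
    generator (truncated-Pareto mutation-frequency spectrum, exponential
    proportional-hazards survival, administrative censoring) and
    MAF-style input/output.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
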