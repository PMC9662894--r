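Package: joinsurv
Title: Joinpoint Survival Models for Trends in Grouped Relative Survival
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits proportional-hazards joinpoint models to grouped life-table
    survival data (relative, cause-specific or overall survival) by single
    calendar year of diagnosis. The calendar-year effect is piecewise linear
    on the log-hazard scale; the number and location of joinpoints are chosen
    by a grid search over candidate years combined with iteratively
    reweighted least squares estimation, with BIC or AIC model selection.
    Reports year-over-year trend measures -- the annual percent change in
    the conditional probability of cancer death (APC_D) and the average
    annual absolute change in t-year cumulative survival (AAC_S) -- with
    delta-method standard errors and confidence intervals, projects survival
    beyond the observed diagnosis years, and includes a simulator that
    generates grouped survival tables from a known joinpoint truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
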