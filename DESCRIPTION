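Package: tgmetrics
Title: Tumour Growth Kinetics Metrics and Survival in Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biexponential modelling of longitudinal tumour burden (RECIST
    sum of longest diameters) with log-normal inter-individual variability,
    and assessment of the model-derived metrics decay rate, re-growth rate
    and time to tumour re-growth as survival predictors. Supports forward
    alignment (clock starts at treatment start, outcome overall survival)
    and reverse alignment (clock starts at disease progression, outcome
    post-progression survival), signed model-based concordance probability
    with bootstrap confidence intervals, Kaplan-Meier and Cox summaries,
    resampled head-to-head test-trial simulation for group-level hazard
    ratio prediction, and a synthetic NSCLC cohort generator emulating
    phase III comparator arms with scheduled scans and progression-triggered
    dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
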