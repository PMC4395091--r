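Package: bayesherd
Title: Bayesian Sequential Binary Decisions Under Social Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling sequential binary decision making under
    social information. Implements a Bayesian belief-updating model in which
    an agent's probability of choosing the correct option is a logistic
    function of the difference between observed correct and incorrect peer
    answers, together with five alternative choice models from the
    collective-behaviour literature. Provides an agent-based simulator of
    two sequential answering protocols (fixed-label and label-shuffled
    round schedules with quenched answers of departed respondents),
    aggregation of response records into condition tables and Weber's-law
    tables, exhaustive grid-search fitting with RMSE model comparison,
    per-question fits with logistic z-collapse diagnostics, Weber's-law
    slope analysis, and parameter-recovery experiments on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
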