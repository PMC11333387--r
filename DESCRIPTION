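Package: lbpburden
Title: Severity Gradients and Treatment-Attributable Burden of Low Back Pain
Version: 0.1.0
Authors@R:
    person("Ilse", "Verbeek", email = "iverbeek@example.org", role = c("aut", "cre"))
Description: Tools to estimate how access to health care shifts the severity of
    low back pain across countries and over time. Pools trial-level
    standardised mean differences for ten intervention classes by
    random-effects network meta-analysis, maps SF-12 health-survey scores to
    disability weights through a logit-linear crosswalk, isolates the
    disability attributable to low back pain net of comorbidity, constructs
    respondent-level no-treatment and full-use-of-optimal-treatment
    counterfactual scores, interpolates country-year disability weights along
    the Health Access and Quality Index, and decomposes years lived with
    disability into averted, avoidable, and unavoidable fractions with
    draw-based uncertainty. A synthetic-data generator with analytic ground
    truth makes every stage testable without access to restricted survey or
    trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
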