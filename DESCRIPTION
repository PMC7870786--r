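Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling with Genomic
    Screening Costs
Version: 0.1.0
Authors@R:
    person("PSM", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for health-economic evaluation of test-directed oncology
    treatment strategies with a decision tree plus partitioned survival
    model. Provides parametric survival machinery (exponential, Weibull,
    gamma, log-normal, log-logistic, Gompertz, generalized gamma,
    Royston-Parmar spline, and mixture/non-mixture cure models) with
    maximum-likelihood fitting and AIC selection; reconstruction of pseudo
    individual-patient data from digitized Kaplan-Meier curves and
    numbers-at-risk (Guyot-style algorithm); a weekly-cycle partitioned
    survival engine with hazard-ratio tail extrapolation, discounted cost
    and QALY accrual, and number-needed-to-screen costing for companion
    genomic testing; incremental cost-effectiveness outputs (ICER, INHB,
    INMB, dominance); and deterministic and probabilistic uncertainty
    analysis (tornado tables, PSA, cost-effectiveness acceptability curves,
    subgroup analysis). A synthetic-data module generates arm-level
    time-to-event data and digitized-curve fixtures so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
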