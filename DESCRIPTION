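Package: kthresh
Title: Supply-Side Cost-Effectiveness Thresholds from Hospital Spending and
    Mortality Panels
Version: 0.1.0
Authors@R:
    person("kthresh", "developers", email = "kthresh@example.org",
           role = c("aut", "cre"))
Description: Estimates a supply-side cost-effectiveness ("k") threshold in two
    steps. First, a Bayesian first-difference panel regression of cause-specific
    (cardiovascular) mortality on per-capita hospital spending is fitted by a
    blocked Gibbs sampler with year and age/gender random intercepts, yielding
    posterior draws of the spending elasticity of mortality. Second, a cohort
    life-table model with age- and time-to-death-dependent quality of life and
    unrelated medical costs translates each elasticity draw into incremental
    discounted costs and QALYs of a marginal spending increase, from which
    cost-per-QALY point estimates, credible intervals, and
    probability-below-value curves are derived. A synthetic-data module
    generates spending/mortality panels from the assumed generative model with
    known truth, and life-table input surfaces, so the whole pipeline is
    testable without access to registry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
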