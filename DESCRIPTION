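Package: inductmod
Title: Hourly Markov Cohort Model of Labour Induction Resource Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic model of labour induction with the
    misoprostol vaginal insert versus the dinoprostone vaginal insert,
    from a hospital resource-use perspective. Calibrates parametric
    cumulative-incidence curves for time to vaginal delivery from printed
    12- and 24-hour summary anchors (with caesarean section as a competing
    outcome), propagates parity-stratified cohorts through an hourly-cycle
    Markov trace, and derives clinical effectiveness, expected
    adverse-event counts, midwife workload (vaginal examinations, vital
    signs monitoring, oxytocin set-up), labour-suite bed occupancy, ward
    capacity gain and births-per-midwife ratios. Includes deterministic
    one-way and multi-way sensitivity analysis, a continuous-monitoring
    scenario, and a seeded individual-level micro-simulation that
    cross-validates the deterministic cohort trace.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
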