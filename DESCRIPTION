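Package: judgebias
Title: Design, Simulation and Analysis of Go/No-Go Judgment Bias Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for latency-based go/no-go judgment bias experiments in
    which subjects are trained to discriminate a rewarded positive cue from
    an unrewarded negative cue and are then probed with ambiguous
    intermediate cues.  Provides pseudorandomized session schedules with
    side-balance constraints, the sequential training-progression state
    machine (cumulative t-test criteria for block training, an exact
    binomial criterion for choice sessions), censoring-aware latency
    statistics, the pessimism index and standardized latencies, fixed- and
    random-effect latency/choice models with Tukey HSD contrasts, and a
    generative behavioural simulator for end-to-end testing and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
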