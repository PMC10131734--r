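Package: meditod
Title: Time-of-Day Preference and Temporal Consistency in Meditation App
    Engagement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses timestamped meditation-app event logs to ask whether
    when people meditate predicts whether they keep meditating. Provides
    session-level filtering and enrollment-day indexing, per-user time-of-day
    preference and timing-entropy features, maintenance outcomes (sessions in
    months six and seven; day of last session), a penalized logistic additive
    model with per-user random intercepts for the daily probability of
    meditating over the first 180 days, per-window linear regressions of the
    outcomes on usage features, k-means clustering of 25-week time-of-day
    trajectories into four-component profiles with weighted cluster
    aggregation, and a seeded synthetic event-log generator so the whole
    pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
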