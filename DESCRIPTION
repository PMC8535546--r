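Package: adherefit
Title: Cluster-Conditioned Ensemble Forecasting of Fitness-App Adherence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether fitness-app users will keep training in their
    fourth month from their first 90 days of workout sessions. Session logs
    are aggregated into daily accumulated workout-seconds series; users are
    grouped by K-means, BIRCH or affinity-propagation clustering on 18
    behavioural features (monthly means, missed-day counts, weekly means);
    a per-user grid-searched time-series forecaster (LSTM or epsilon-tube
    support vector regression over 7-day sliding windows) is trained for
    every user, and a new user's fourth month is predicted as the
    elementwise mean forecast of the cluster ensemble, then binarised into
    adherent or non-adherent. Includes a seedable synthetic-cohort
    generator, leave-one-user-out evaluation and confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
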