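Package: tweetsignal
Title: Early Warning of Public Health Threats from Social Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An offline, testable event-based surveillance pipeline for short
    social-media posts: seeded synthetic tweet streams with injectable
    outbreak bursts, two-step gazetteer geolocation (a trainable
    location-word classifier followed by vector-space matching against a
    GeoNames-style gazetteer), aggregation into topic-by-region daily count
    series, aberration detection with a modified EARS algorithm featuring
    Farrington-style outlier downweighting, alert generation, and the
    surveillance-evaluation statistics that go with such a system (confusion
    metrics, general and specific positive predictive value, inter-rater
    agreement, Wald confidence intervals, timeliness summaries and the
    one-sided Wilcoxon signed-rank test).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
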