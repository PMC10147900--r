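Package: outagegrid
Title: County-Level Power Outage Exposure, Severe Weather Co-Occurrence,
    and Vulnerability Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising county-level power outage exposure
    from high-frequency customers-without-power feeds: reliability
    screening of intermittent feeds, threshold-based detection of 1+ and
    8+ hour outage events with SAIFI/SAIDI-like exposure metrics,
    rule-based classification of county-days into severe weather and
    climate event types with co-occurrence ratio statistics, and
    bivariate local Moran (LISA) clustering of outage burden against
    social and medical vulnerability with permutation inference and
    false discovery rate control. Includes a synthetic-data generator
    with recorded ground truth (planted outage events, reporting gaps,
    weather coupling, vulnerability clusters) so the full pipeline is
    testable without proprietary outage feeds.
License: MIT + file LICENSE
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
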