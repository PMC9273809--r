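Package: qldsmct
Title: Meaningful Change Thresholds for the Quality of Life in Depression Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates within-patient meaningful change thresholds (MCTs) for
    the Quality of Life in Depression Scale (QLDS) from two-visit clinical
    trial data, using anchor-based responder analysis (MADRS severity
    categories, CGI point changes, EQ-VAS regression projection) and the
    half-standard-deviation distribution method, with triangulation of the
    candidate thresholds into a recommended integer MCT. Includes a
    synthetic two-visit cohort generator with configurable marginal and
    rank-correlation structure so the full pipeline can be exercised and
    validated without access-restricted patient-level data, plus stratified
    empirical CDF responder curves and separation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
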