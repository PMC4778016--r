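Package: borealfire
Title: Fire-Climate Regime Statistics for Boreal Fire Histories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical tools linking boreal forest fire activity to
    ocean and climate state: detection of large fire years from multi-site
    fire records against a binomial null, sequential t-test regime shift
    detection (Regime Shift Index with Huber outlier down-weighting and
    AR(1) prewhitening), a bootstrap test of fire-year clustering in cold
    temperature regimes, and teleconnection statistics between a scalar
    index and gridded monthly fields (correlation maps with
    effective-sample-size adjusted significance, Monte-Carlo field
    significance, moving-window correlations, and superposed epoch
    analysis).  A seeded synthetic-data generator emulates the statistical
    structure of annual fire records, proxy series and teleconnected
    fields so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
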