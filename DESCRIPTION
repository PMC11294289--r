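Package: voxplp
Title: Polygonal Language Profiles from Verbal Operant Assessment Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts trial-level verbal operant experimental (VOX) analysis
    records -- responses probed under tact, mand, echoic, and sequelic
    conditions -- into polygonal language profiles on a four-axis radar
    chart, and computes their shape descriptors: area, maximal-area axis
    ordering, centroid, centroidal distance, quadrant-convergence shares,
    and the first moment of area Q = A(C - R) relative to a circumscribing
    property space of radius C. Includes a Cochran Q related-samples test of
    functional independence, longitudinal descriptor series, cross-speaker
    profile comparison, radar-chart and time-series visualization, a seeded
    synthetic-data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
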