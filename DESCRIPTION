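Package: heatwaveCA
Title: Percentile-Based Heatwave Indices, Bias Correction, Trends and
    Attributable Mortality for Central Asian Temperature Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale climate-health analysis pipeline for daily
    station temperature records. Computes calendar-day 90th-percentile
    threshold climatologies and the yearly warm-day/night and heatwave
    indices built on them (TX90p, TN90p, HWN, HWF, HWD, HWM, HWA),
    applies mean-variance ("hybrid semi-parametric") bias correction to
    climate-model-like series with equal-weight ensembling, tests trends
    with the Mann-Kendall statistic and Sen's slope, classifies heatwave
    magnitude into severity categories, and estimates heatwave-attributable
    all-cause mortality from relative-risk values and demographic tables.
    A synthetic-data module generates reference ("pseudo-reanalysis") and
    model ("pseudo-GCM") daily series plus demographic tables with known,
    recoverable structure so every stage is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
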