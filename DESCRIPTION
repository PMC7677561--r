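Package: ctcstream
Title: Temporal Sampling Statistics for Rare Circulating Tumor Cell Detection Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing timestamped detection-event streams from
    continuous in vivo cytometry of rare circulating tumor cells (CTCs).
    Converts scan-time intervals to equivalent blood-sample volumes, counts
    detections in sliding or non-overlapping windows, computes the
    deviation-from-scan-mean (DFSM) statistic with Poisson reference
    distributions, quantifies overdispersion through zero-intercept
    variance-versus-mean fits, summarises 24-hour diurnal variability, and
    evaluates blood-sampling strategies that trade sample volume against
    temporal spread. Includes seeded generators for homogeneous,
    change-point, merged (superposed) and Markov-modulated Poisson event
    streams and for diurnal multi-scan sessions, so every analysis stage is
    testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
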