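Package: plaquekin
Title: Amyloid Aggregation Kinetics, Plaque Zonation, and Expression
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for three quantitative procedures common in studies of
    amyloid-beta pathology: (1) fitting Thioflavin-T plate-reader
    aggregation kinetics with the unseeded primary plus secondary
    nucleation model, including normalization, half-time extraction and
    deterministic multi-start global fitting; (2) partitioning fluorescent
    amyloid plaques into center and border zones by an intensity-fraction
    rule and quantifying a second marker channel per zone with paired
    enrichment tests; (3) qPCR virtual-mRNA quantification from cycle
    thresholds and standard-curve slopes, densitometry normalization and
    the associated group-comparison statistics. A synthetic-data module
    generates plate traces, two-channel plaque images and ct tables with
    ground truth so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
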