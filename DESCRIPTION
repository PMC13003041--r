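Package: axopath
Title: Quantitative Neuropathology of AAV-A53T Alpha-Synuclein Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, scriptable re-implementation of a quantitative
    neuropathology workflow for AAV-A53T alpha-synuclein mouse models of
    Parkinson's disease: automated counting of axonal swellings in
    immunostained microscopy z-stacks (8-bit conversion, contrast inversion,
    rolling-ball background subtraction, median smoothing, contrast
    enhancement, moment-preserving thresholding, 3-D particle analysis with
    physical size filters), region-of-interest optical densitometry with
    anatomical background normalisation, optical-fractionator stereology and
    Cavalieri volume estimation, glial positive-area-fraction quantification,
    and a composite Axonal Degeneration Index (ADI) built from per-time-point
    z-scores of tyrosine hydroxylase optical density and swelling counts with
    a three-stage classification rule. Includes synthetic-data generators
    (image stacks with known swelling ground truth; animal cohorts with
    sex-specific degeneration dynamics) so every stage is testable without
    raw data, plus the group statistics the workflow reports (Mann-Whitney U
    with tie correction, Shapiro-Wilk, two-way ANOVA, ANCOVA, power
    calculations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    igraph
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
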