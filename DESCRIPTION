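Package: serrmorph
Title: Morphometrics and Comparative Statistics of Owl Leading-Edge Serrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based measurement of owl wing leading-edge serration
    shape (inclination angle, tip-displacement angle, curved serration
    length), classification of leading-edge elements as smooth, denticulate
    or serrated, an interdependence-aware Monte-Carlo Mann-Whitney
    significance procedure with fraction-of-significant-runs banding,
    max-normalized UPGMA species dendrograms with an activity-bipartition
    check, and a hierarchical synthetic-data generator calibrated to
    published species means, tied together by an end-to-end reporting
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
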