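Package: lmschart
Title: LMS Growth-Reference Construction for Birth Weight Centile Charts
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and use of growth-reference centile charts with
    the LMS (Box-Cox-Cole-Green) method, motivated by birth-weight-for-
    gestational-age charts for infants with Down syndrome. Provides the
    BCCG distribution and all centile/z-score arithmetic, penalized
    maximum-likelihood fitting of smooth L, M and S curves with a log-link
    median and a constant sex offset, a seeded synthetic birth-register
    simulator, an end-to-end analysis pipeline (record selection, chart
    fitting, centile tables, secular-trend and missingness regressions,
    reference-chart comparison), and readers/writers for the record and
    chart file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
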