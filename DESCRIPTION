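Package: sgoftrace
Title: Sequential Goodness-of-Fit Multiple Testing and the SGoFicance Trace
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the SGoF (Sequential Goodness-of-Fit) multiple-testing
    procedure, an exact binomial meta-test that compares the number of
    p-values below a working threshold gamma with the number expected under
    the intersection null, declaring the K - b + 1 smallest p-values as true
    effects upon rejection.  Provides the SGoFicance Trace, a four-panel
    diagnostic that sweeps gamma over (0,1) and displays the meta-test
    log-significance, the number of declared effects, a plug-in estimated
    false discovery rate, and the realized p-value threshold.  Includes a
    Monte-Carlo simulation framework for power and false-discovery-proportion
    evaluation against the Benjamini-Hochberg baseline, a reader and writer
    for the SGoF p-value file format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
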