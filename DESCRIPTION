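Package: crossfreq
Title: Cross-Frequency Coupling Analysis of Trial-Structured LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band decomposition, Hilbert-based phase-amplitude and
    amplitude-amplitude coupling, and ANOVA orientation/stimulus selectivity
    screening for trial-structured local field potential (LFP) recordings.
    Includes a synthetic session generator with injectable, orientation-tuned
    cross-frequency coupling, a directory-based session-bundle format, an
    end-to-end pipeline runner and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    optparse
Config/testthat/edition: 3
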