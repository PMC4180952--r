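Package: oscarrest
Title: Cell-Cycle Transcriptional Oscillations Under Checkpoint and CDK Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates synchronized-population transcript time courses from
    budding-yeast cell-cycle arrest experiments (CDK perturbations and
    checkpoint arrests), calls high-confidence periodic genes by a
    multi-algorithm intersection consensus with permutation p-values and
    Benjamini-Hochberg FDR control, classifies per-gene arrest behaviors
    across conditions, aligns conditions at the 50%-budded anchor, and tests
    transcription-factor target overrepresentation in behavior clusters with
    hypergeometric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite
Config/testthat/edition: 3
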