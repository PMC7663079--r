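Package: binest
Title: Nestedness Metrics and Maximum-Entropy Null Models for Binary
    Bipartite Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the nestedness of binary bipartite networks
    (e.g. plant-pollinator webs) with eight indices: Atmar-Patterson
    temperature, the Manhattan-distance index (NMD), NODF and
    stable-NODF, Brualdi-Sanderson discrepancy, the robustness-based
    NIR index, and the raw and normalized spectral radius.  Provides
    the maximally packed configuration, the canonical perfectly nested
    reference matrix and its isocline of perfect nestedness, a
    maximum-entropy / maximum-likelihood null ensemble (bipartite
    configuration model) that preserves both degree sequences on
    average, ensemble z-scores, seeded synthetic network generators,
    and the rank-correlation and multilinear-regression machinery to
    study how the indices depend on network size, fill and
    eccentricity.  A small command-line front end supports batch
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
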