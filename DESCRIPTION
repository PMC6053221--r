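Package: presynmorph
Title: Quantitative EM Morphometry of Presynaptic Terminals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Morphometric analysis of traced transmission-EM annotations of
    presynaptic terminals: classification of the terminal membrane into
    active-zone and glial-facing compartments, vesicle-to-membrane distance
    distributions with kernel-density pool-peak identification (Silverman
    bandwidth), near-membrane vesicle contingency analysis (Fisher's exact
    test), glial coverage and apposition-gap morphometry, nonparametric
    group comparisons (Kruskal-Wallis with Dunn's post hoc), and a synthetic
    annotation generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
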