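Package: ergpanel
Title: Stability-Based Selection and Evaluation of Estrogen-Responsive Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives stable marker panels of estrogen-responsive genes (ERGs)
    from replicated treated/control expression profiles. Ranks genes by the
    coefficient of variation |SD/Av| of their per-replicate log2 response
    ratios, selects balanced up-/down-regulated panels, and evaluates panel
    reproducibility by Pearson correlation of replicate profiles over nested
    gene sets. Includes volcano-table summaries, hypergeometric
    over-representation analysis with Benjamini-Hochberg FDR, a rule-based
    ER-subtype classifier operating on tabulated ChIP peak evidence, and a
    synthetic-data generator for end-to-end testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
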