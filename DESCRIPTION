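Package: orgscreen
Title: Organizer Synexpression Screening from Multi-Tissue Expression Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of embryonic organizer signatures from multi-tissue
    expression screens. Fits per-comparison differential expression with an
    empirical-Bayes moderated t-statistic and Benjamini-Hochberg false
    discovery rate control, combines enriched/depleted calls across contrasts
    with a Boolean algebra to derive a synexpression gene set, scores
    candidate embryonic regions for concordance with the signature, and
    analyses explant co-culture assays with exact two-tailed Fisher tests.
    Includes a planted-signal simulator emulating a 9-tissue triplicate
    microarray design for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
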