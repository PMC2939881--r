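Package: dupcensus
Title: Full-Text Similarity Census for Duplicate Publication Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a corpus-scale census of text similarity in structured
    scientific articles. Parses JATS full-text XML into articles with
    IMRaD-classified sections, computes an identity-normalised weighted
    term-overlap similarity ratio between text units (full texts, abstracts,
    sections, paragraphs), runs thresholded all-vs-all scans over an inverted
    index, and derives duplicate-census statistics: frequencies of similar
    pairs, shared-author odds, abstract-versus-full-text contingency analysis
    with log odds ratios, conditional probabilities by section class, ratio
    distributions and correlations, and review-article strata. Includes a
    synthetic corpus generator that plants duplicate pairs with controlled
    location, copy fraction and author overlap, recording ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
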