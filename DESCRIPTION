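Package: lexner
Title: Lexicon-Enhanced Chinese Named Entity Recognition with
    Criss-Cross Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for character-level Chinese named entity recognition in
    specialised domains such as agricultural disease and pest text.
    Implements statistics-based new-word detection (word frequency, mutual
    information and branching entropy over n-gram candidates) and lexicon
    construction via dictionary segmentation; BMES word-set (Softlexicon)
    character features with frequency weighting and an attention-based
    extension that learns per-set importance weights through criss-cross
    attention; a BiLSTM-CRF sequence tagger augmented with a parallel
    criss-cross attention block, trained by stochastic gradient descent
    through a built-in reverse-mode automatic differentiation engine; and
    strict entity-level precision/recall/F1 evaluation.  A seeded synthetic
    corpus generator emulates the statistical structure of domain corpora
    (multi-character terms, nested words, uneven category counts) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
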