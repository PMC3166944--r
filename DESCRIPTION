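Package: relenz
Title: Enzyme-Disease Relation Mining from Literature Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A sentence-level text-mining chain for enzyme-disease
    relations in PubMed-style titles and abstracts. Dictionary-based
    recognition of enzyme (EC number) and disease mentions, sentence
    co-occurrence mining, tf-idf feature vectors with entity removal or
    replacement preprocessing, per-category binary support vector machine
    classification into four relation categories (causal interaction,
    ongoing research, diagnostic usage, therapeutic application), a
    four-level ensemble-vote confidence scheme, k-fold cross-validation
    with vertically averaged ROC curves, and a seeded synthetic corpus
    generator so the whole chain is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    xml2,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
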