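Package: drugchar
Title: Example-Based Classification of Drug Characteristics from Literature Abstracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines a corpus of biomedical abstracts for tokens that discriminate
    a binary drug characteristic (therapeutic class, adverse effect, interaction
    potential) given only a list of positive-example drugs. Abstracts matched to
    each drug are tokenized into bags of tokens; per-drug token scores
    (conditional document frequency, conditional term frequency, and its
    inverse-conditional-document-frequency weighting) are computed; rare and
    corpus-size-correlated tokens are eliminated; surviving tokens are ranked by
    ROC AUC against the positive drug set; and the top-ranked token scores feed
    naive Bayes, inverse-distance k-nearest-neighbour, and support vector
    machine classifiers. Performance is estimated by stratified cross-validation
    with leakage-free per-fold feature selection, Hanley-McNeil standard errors,
    and a one-sided test against chance. A synthetic-corpus generator with
    planted rare, common-correlated, and discriminative tokens makes every
    pipeline stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
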