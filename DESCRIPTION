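Package: sentisess
Title: Lexicon-Based Sentiment Analysis of Clinical Session Records with
    Inter-Rater Agreement Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for automated sentiment analysis of clinician-written
    session records: de-identification placeholders, tokenization and
    cleaning, lexicon-based polarity scoring with bigram/trigram negation and
    intensifier handling, relevance filtering, score standardization with a
    data-driven neutral band, and categorical mapping. Validation tooling
    includes weighted Cohen's kappa and the two-way mixed absolute-agreement
    single-measure intraclass correlation ICC(A,1) with F-based confidence
    intervals, per-patient stratification, qualitative match audits, and a
    synthetic corpus and rater simulator with known ground truth so every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
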