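Package: comention
Title: Context-Aware Co-Occurrence Scoring of Entity Co-Mentions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores pairwise associations between named entities mined from
    a sentence-level co-mention corpus. Co-mentions are weakly labeled by
    distant supervision against a gold standard of known pairs (with
    grey-listing and ontology propagation), a logistic sentence classifier
    over averaged unigram and hashed-bigram word embeddings assigns each
    sentence a probability of stating an association, and per-document
    maxima of these scores are aggregated corpus-wide into a count times
    observed-over-expected co-occurrence score. Evaluation uses pair-level
    train/test splitting, cross-validation over the aggregation exponent,
    class-prior-adjusted precision-recall analysis and bootstrap model
    comparison. A synthetic co-mention corpus generator with controllable
    context informativeness supports benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
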