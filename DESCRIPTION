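Package: sentmatch
Title: Fine-Grained Sentence Matching for Species Identification from
    Layperson Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies fine-grained categories (e.g. bird or flower
    species) by matching free-text layperson descriptions of an image
    against an expert document corpus that contains exactly one article
    per class. A Siamese sentence comparator is trained from
    automatically synthesized positive/negative/neutral sentence pairs
    -- no expert class labels are used -- and its pairwise scores are
    averaged into per-document scores, posteriors and rankings. Includes
    a second training stage with a batch-level score-distribution
    regularizer to bridge the domain gap between layperson captions and
    expert prose, classical retrieval baselines (TF-IDF, Okapi BM25,
    embedding cosine), top-k/mean-rank evaluation, and a synthetic
    attribute-world generator for fully offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
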