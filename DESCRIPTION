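Package: sigvecta
Title: Aggregation and Multi-View Analysis of Gene Expression Signature Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Local analysis of collections of gene expression signatures:
    characteristic-direction differential expression by regularized linear
    discriminant analysis with permutation-based significance, gene-set
    enrichment with a hypergeometric p-value and rank-deviation combined
    score, cosine-similarity matching against compound signature libraries
    (mimickers and reversers), and collection-level aggregate matrices with
    principal component analysis and hierarchical heatmap ordering, exported
    as a reproducible report bundle. Includes a deterministic synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
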