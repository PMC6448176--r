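Package: problistr
Title: Semantic Grouping and Post-Coding of EHR Problem Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups short (up to 50 characters) free-text diagnosis entries
    from electronic health record problem lists into semantic topics and
    post-assigns ICD-10 codes to uncoded entries. Entries are normalized by
    a minimal German language pipeline (tokenization, lowercasing, stopword
    removal, Snowball stemming, pattern stripping), vectorized as tf-idf
    weighted character 3-grams, and clustered with average-linkage (UPGMA)
    agglomerative clustering on cosine distances. The dendrogram cut height
    is inferred by maximizing a pairwise F-measure against the partially
    available ICD-10 codes; uncoded items inherit the code of their most
    similar coded cluster neighbour. Includes optional latent semantic
    analysis (truncated SVD) of the term-document matrix, a full evaluation
    battery (precision/recall/F, compression rates, Chernoff-bound sample
    size estimation), and a synthetic problem-list generator for end-to-end
    testing without protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    ape,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
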