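Package: semipnmf
Title: Semi-Supervised Projective Non-Negative Matrix Factorization for
    Expression-Based Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns shared non-negative cluster centroids from partially
    labeled gene-expression samples by projective non-negative matrix
    factorization with a centroid-consistency penalty and a local
    coordinate coding penalty. Labeled samples have their coefficient
    rows pinned to one-hot class indicators; unlabeled samples are
    classified by the argmax of their learned coefficients. Includes
    multiplicative-update optimization with guaranteed monotone descent,
    expression-matrix preprocessing (box bounding, ratio/variation gene
    filtering, k-nearest-neighbour imputation), a synthetic three-class
    toy-data generator, and an evaluation harness (confusion matrices,
    per-class sensitivity and specificity, leave-one-unlabeled
    cross-validation, labeled-count accuracy curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
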