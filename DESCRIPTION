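Package: topocalc
Title: Topological Filtering and Classification of Microcalcification Image Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Persistent-homology tools for 8-bit grayscale image patches of
    mammographic microcalcifications. Computes sublevel-set cubical persistence
    (H0 components and H1 loops), applies multi-level noise filtering of
    persistence diagrams by fraction of the maximum lifespan, vectorises
    diagrams into persistent-entropy and persistence-image features, and
    evaluates benign/malignant separation with a cross-validated
    multi-classifier harness. Includes a deterministic synthetic patch
    generator so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    withr,
    png,
    e1071,
    rpart,
    class,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    pracma,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
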