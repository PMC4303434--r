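Package: gie
Title: Geographic Interpolation of Endemism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-free delimitation of areas of endemism from species
    point-occurrence records by Geographic Interpolation of Endemism (GIE).
    Species ranges are summarized by the centroid of their records and the
    distance to the farthest record, sorted into range-size categories, and
    interpolated as truncated Gaussian areas of influence whose cell-wise sum
    (the kernel index) is rasterized per category, min-max standardized, and
    combined into a consensus surface. Areas of endemism are read off the
    consensus as isolines and connected components, each supported by its
    synendemic species. Includes rarefaction-based centroid stability,
    elongation and disjunction screening, scheme-comparison correlations,
    presence/absence grid-matrix export for parsimony analysis of endemism,
    and a synthetic-landscape generator with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
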