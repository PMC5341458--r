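Package: rootproxy
Title: Likelihood-Weighted Root Phenotyping from Multi-Well Plate Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Threshold-free phenotyping of seedling root systems grown in
    multi-well transparent plates. Instead of binarising each image, a
    per-pixel likelihood of root material is computed from multi-source
    shortest paths over an intensity-weighted pixel graph, seeded at local
    brightness maxima in the top strip of each well. A catalogue of
    likelihood-weighted proxy traits (centroid, mass, bounding-box and
    quantile depths, quadrant masses, Sobel orientation histograms) is then
    measured per well, together with top-down shoot traits (leaf area and
    hue). Includes a deterministic synthetic plate generator with ground
    truth, a batch pipeline that writes one traits CSV per run, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    png,
    tiff,
    yaml,
    withr,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    MASS,
    EBImage,
    optparse
Config/testthat/edition: 3
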