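Package: rangecomplex
Title: Higher-Order Spatial Overlap Networks from Seasonal Core Ranges
Version: 0.1.0
Authors@R: person("Range", "Complex Developers", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Analyses higher-order spatial overlap among individual seasonal
    core ranges. Computes intersection/union ratios for subsets of range
    polygons (exact planar boolean areas via a slab sweep), rescales them by
    the theoretically optimal overlap w* = 1/(n+1) into a filtration index,
    builds a downward-closed filtered simplicial complex, computes persistent
    homology over GF(2) (barcodes and Betti curves), and summarises
    complementarity (filtration complementarity index) and maximal simplicial
    degree centrality. Includes a synthetic core-range and phenology
    generator so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
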