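Package: srev
Title: Self-Returning Excluded-Volume Chromatin Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic generator of nucleosome-resolution chromosome
    conformations from self-returning random walk rules with excluded
    volume, plus the observable suite used to characterize them: contact
    probability and end-to-end scaling versus genomic distance, chromatin
    volume concentration, coordination numbers, pair correlation and
    packing exponent D, and an image-based packing-domain identification
    pipeline operating on voxelized density stacks.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
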