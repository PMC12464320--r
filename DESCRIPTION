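Package: dropletAST
Title: Single-Cell Antibiotic Susceptibility Analysis for Droplet Microfluidics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for droplet-microfluidics single-cell
    antibiotic susceptibility testing (AST). Detects water-in-oil droplets
    in bright-field micrographs, classifies them as growth-positive or
    growth-negative from grey-level co-occurrence matrix (GLCM) texture
    features with k-means clustering, turns per-concentration droplet
    counts into normalized proliferating fractions, fits the Gompertz
    (Weibull-type) survival function to the dose-response profile, and
    derives the full individual-MIC (iMIC) statistic suite: distribution
    mode, closed-form moments, threshold concentrations, and the degree
    of heteroresistance. Includes a synthetic-data module that emulates
    Poisson single-cell encapsulation and droplet imaging with known
    ground truth, for validation and benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    withr,
    EBImage,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
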