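Package: mammotrace
Title: Probabilistic Breast-Boundary Tracing in Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sequential probabilistic tracing of the breast (and pectoral
    muscle) boundary in 8-bit grayscale mammograms. Each next boundary pixel
    is chosen to maximize the product of a calibrated SVM probability of
    local binary pattern (LBP) window texture, a bivariate-Gaussian
    smoothness density over consecutive segment slopes, and a Laplace prior
    that sharpens high texture probabilities. Includes boundary evaluation
    metrics (mean perpendicular deviation and a curve-smoothness measure),
    greedy active-contour and threshold baselines, and a seeded generator of
    mammogram-like phantom images with exact ground-truth boundaries so the
    full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    EBImage,
    jsonlite,
    png,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
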