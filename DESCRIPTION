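Package: maizekern
Title: Kernel Counting on Maize Ear Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Automatic recognition and counting of kernels on maize ears from
    single-side RGB photographs. Implements a five-stage pipeline: Gaussian
    pyramid compression, mean-shift filtering with colour-threshold background
    separation, colour-deconvolution edge enhancement in an offset Lab space,
    local adaptive mean thresholding, and Gaussian-smoothed local-maxima kernel
    recognition. Ships a Hough-circle baseline, point-matching evaluation
    metrics, and a synthetic ear-image generator with exact ground truth so
    every stage can be validated without field photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
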