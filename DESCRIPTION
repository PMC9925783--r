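Package: glomix
Title: Simulation and Decoding of Glomerular Odor Responses in Novel Backgrounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how odor targets can be identified within
    unpredictable background mixtures from olfactory-bulb glomerular
    activation patterns. Generates per-animal glomerular atlases and noisy
    trial instantiations under a multiplicative mean-variance noise model
    with a correlated/uncorrelated decomposition, quantifies intrinsic-signal
    imaging movies into per-ROI z-score responses, synthesizes virtual odor
    mixtures through a saturating nonlinearity, and benchmarks four decoder
    families (single-glomerulus auROC thresholding, L1-regularized linear
    SVM and logistic regression, nearest-neighbor template matching) against
    Lasso sparse deconvolution with a go/no-go concentration readout.
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
    glmnet,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
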