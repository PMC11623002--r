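Package: splitfed
Title: Split Federated Learning with Conditional GAN Augmentation for
    Imbalanced Grayscale Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study collaborative training of convolutional image
    classifiers when data are private, decentralized and severely
    class-imbalanced. Implements split federated learning (SFL): a
    ResNet18-style network is cut into a client front and a server back that
    exchange cut-layer activations ("smashed data") and gradients, with
    federated averaging of client-side weights across simulated clients, plus
    plain federated learning (FL) and split learning (SL) baselines and a
    centralized reference trainer. Class imbalance is countered with a
    label-conditioned generative adversarial network (cGAN) that synthesizes
    minority-class images, followed by CLAHE contrast enhancement and
    resizing. A deterministic phantom-image generator produces grayscale
    datasets with class-dependent geometry so the full pipeline is testable
    without any external imaging data. The underlying convolutional network
    engine (convolution, transposed convolution, batch normalization, pooling,
    Adam) is implemented in C++ with single-precision BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
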