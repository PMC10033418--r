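Package: mitoscape
Title: Quantitative Mapping of Mitochondrial Network Structure in Volume Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for spatial and structural mapping of
    mitochondrial networks in serial block-face electron microscopy (SBEM)
    volumes and fluorescence time-lapse imaging. Provides a ground-truthed
    synthetic scene generator (anisotropic EM-like volumes with an ellipsoidal
    nucleus, capsule-shaped mitochondria and spherical lipid droplets), a
    trinary nucleus/mitochondria/background semantic segmentation network
    (U-Net style encoder-decoder with residual blocks and atrous spatial
    pyramid pooling) with its training recipe and evaluation metrics, a
    classical median-filter/threshold/watershed instance segmentation
    pipeline, per-mitochondrion 3D morphometry (volume, surface area, length,
    sphericity), minimum mitochondrion-to-nucleus distances via a quartic
    point-to-ellipse solver and anisotropy-aware 3D distance transforms, a
    time-lapse mitochondrial motility statistic (displacement-ratio
    regression slope), and classification of mitochondria into perinuclear,
    peri-droplet and cytoplasmic subpopulations together with PET-tracer
    uptake phenotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
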