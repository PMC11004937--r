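Package: RegionGAN
Title: Region-Aware Generative Adversarial Translation of Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-to-image translation for roughly paired microscopy data.
    Images are partitioned into mutually exclusive square regions of a
    "tolerance size" that is selected automatically by maximising the
    feature-space Pearson correlation of randomly cropped source and target
    regions. Training patches are drawn by a global sampling rule that favours
    well-correlated and rare regions, and a pair of shared-latent generators is
    trained against (N+1)-class region-aware discriminators with
    cycle-consistency and reconstruction losses. Includes intensity
    normalisation, Sobel-Feldman gradient channels, point-based and
    correlation-refined affine registration, overlapped tiled inference,
    MS-SSIM/PSNR evaluation, and a synthetic generator of roughly paired
    datasets with controllable misalignment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'RegionGAN-package.R'
    'cli.R'
    'inference.R'
    'io.R'
    'layers.R'
    'losses.R'
    'metrics.R'
    'networks.R'
    'preprocess.R'
    'regions.R'
    'synthetic.R'
    'tolerance.R'
    'training.R'
    'utils.R'
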