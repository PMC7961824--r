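Package: pamvasc
Title: Quantitative Vasculature Assessment for Photoacoustic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free quantitative assessment of vascular networks imaged
    by optical-resolution photoacoustic microscopy (OR-PAM). Reconstructs
    maximum-amplitude-projection (MAP) and depth-resolved images from raw
    RF volumes via the Hilbert-transform envelope, segments vessels with a
    multi-scale Hessian (Frangi-type) vesselness filter followed by adaptive
    thresholding, skeletonization and the Euclidean distance transform, and
    computes five vascular metrics: PA signal, vessel diameter, vessel
    density, perfused vessel density, and box-counting vessel complexity.
    Includes sliding-window quantitative parameter maps, ROI time-course
    analysis with control-normalized percent changes for photodynamic
    therapy (PDT) monitoring, and a synthetic vessel-phantom generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
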