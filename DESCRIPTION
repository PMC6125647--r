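Package: fibriwave
Title: Atrial Fibrillation Detection from ECG via Wavelet Scalograms and a 2D
    Convolutional Network
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements an end-to-end pipeline for automatic detection of
    atrial fibrillation (AF) from single-lead ECG: translation-invariant
    dyadic (a trous) wavelet denoising with db4, proportional five-beat
    segmentation anchored at annotated R peaks, continuous wavelet transform
    (db5) scalogram construction, and a 2D convolutional neural network
    classifier trained by stochastic gradient descent, together with a
    synthetic two-class ECG generator, balanced record-disjoint dataset
    splitting and binary classification metrics (sensitivity, specificity,
    positive predictive value, accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: Classification, Preprocessing, TimeCourse
RoxygenNote: 7.3.3
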