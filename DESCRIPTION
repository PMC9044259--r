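Package: earnet
Title: Lightweight Wheat-Ear Detection with Shuffle Polarized Self-Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A single-stage, anchor-based detector for wheat ears (heads) in
    field images, built for CPU-scale experimentation. Implements an
    asymmetric-bottleneck (ASB) backbone with multi-scale P3/P4/P5 taps, the
    Shuffle Polarized Self-Attention (SPSA) block, the TanhExp activation,
    IOU/GIOU/CIOU bounding-box losses, a PANet-style neck with three YOLO
    detection heads, greedy NMS and average-precision evaluation, and a
    synthetic wheat-field scene generator with the standard augmentation
    suite (scale, mirror, rotate, saturation, Mosaic). The network engine
    (convolutions, batch normalization, attention, Adam with cosine
    annealing) carries explicit forward and backward passes with Rcpp
    convolution kernels, so the full pipeline trains and evaluates end to
    end on a CPU without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
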