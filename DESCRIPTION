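Package: mucorec
Title: Mucosal Recovery Mapping for Endoscopic Submucosal Dissection Specimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for reconstructing mucosal recovery maps from whole-slide
    images of endoscopic submucosal dissection (ESD) specimens of early gastric
    cancer. Tiles slides and RGB annotation masks into fixed-size patches,
    segments each patch into cancerous, intestinal-metaplasia and normal mucosa
    classes with a squeeze-and-excitation ResNet-34 U-Net trained under a
    combined soft-Jaccard and cross-entropy loss, reassembles patch predictions
    into slide-level annotations, and maps section-level annotations back onto
    the macroscopic specimen photograph. Includes a self-contained CNN engine
    (reverse-mode autodiff over RcppArmadillo convolution kernels), MIoU and
    Dice evaluation, a synthetic histology generator for end-to-end testing,
    and rigid section placement with normalized cross-correlation refinement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
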