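Package: toothseg
Title: Tooth Segmentation and Tissue Classification in MicroCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic segmentation and classification of a single tooth in
    micro computed tomography (MicroCT) volumes. A three-dimensional
    Selective Binary and Gaussian Filtering Regularized Level Set (GFRLS)
    driven by a region-based signed pressure force extracts the tooth; an
    improved pulse-coupled neural network (PCNN) with a hierarchical graded
    pulse output classifies enamel, dentine and pulp; structure volumes are
    estimated by quasi-Monte Carlo integration over Halton points. Includes
    the standard overlap and volume-agreement statistics (Dice similarity,
    sensitivity, specificity, relative error, mean absolute deviation,
    correlation), a deterministic synthetic tooth-phantom generator with
    exact ground truth, readers and writers for TIFF, NIfTI, PNG-slice and
    raw volumes, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
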