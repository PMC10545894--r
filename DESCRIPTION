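Package: msivigor
Title: Multispectral Image Based Rice Seed Vigour Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive seed vigour testing from multispectral petri-dish
    acquisitions. Provides a data model and I/O for 19-band + RGB spectral
    stacks, a synthetic dish-scene generator with ground truth, classical
    per-seed ROI detection, dataset construction with dihedral augmentation,
    the MsiFormer residual-CNN + linear-attention germination classifier with
    a manual-backpropagation training loop, confusion-matrix and ROC/AUC
    evaluation, CIELab colorimetric quantification of tetrazolium staining,
    normalized canonical discriminant analysis (nCDA) of pixel spectra, and
    conventional vigour statistics (germination rate, vigor index,
    coefficient of variation, seed morphology).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
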