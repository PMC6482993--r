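Package: oirquant
Title: Quantification of Retinal Neovascularization Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-analysis toolkit for quantifying pathological angiogenesis
    in rodent models of retinal disease. Implements automatic histogram
    thresholding (Otsu between-class variance and Huang-Wang fuzzy entropy),
    a four-threshold segmentation pipeline for oxygen-induced retinopathy
    (OIR) flatmounts that partitions the retina into neovascular, avascular
    and normally vascularized areas, volumetry of laser-induced choroidal
    neovascularization (CNV) lesions from fluorescence z-stacks, skeleton
    based vessel-network metrics (total length, branching index,
    lacunarity), and densitometry of duplicate-spot phospho-kinase array
    membranes with Benjamini-Hochberg false-discovery-rate control. A seeded
    synthetic-data generator produces flatmount images, lesion stacks and
    array membranes with exact ground truth, so every pipeline stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    tiff,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
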