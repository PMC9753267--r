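Package: carsPlaque
Title: Automated Staging of Atherosclerotic Plaque in CARS Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An automated image-classification pipeline for label-free
    coherent anti-Stokes Raman scattering (CARS) microscopy of
    atherosclerotic plaque. Images of lipid-laden foam-cell clusters are
    contrast-adjusted and sharpened, segmented by four parallel methods
    (Otsu thresholding, independent foam-cell thresholding,
    marker-controlled watershed and Gabor-textured k-means), and described
    by a 27-feature morphology panel combining first-order statistics,
    shape descriptors and Haralick co-occurrence textures. Features are
    refined by an interclass coefficient-of-variation rule and by
    chi-square filter-type selection, then staged by tuned k-nearest
    neighbour, decision-tree and one-vs-one multiclass support vector
    machine classifiers into early fatty streak (EFS), early fibroatheroma
    (EF) and advancing atheroma (AA). A synthetic foam-cell phantom
    generator with per-image ground-truth masks supports benchmarking of
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    e1071,
    rpart,
    withr,
    jsonlite,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
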