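Package: vertphen
Title: Vertical Phenotyping of Rice from Front-View Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts vertical architectural traits of single potted rice
    plants from front-view RGB images. Segments the plant by HSV colour
    thresholding, derives silhouette geometry (contour, convex hull,
    droop-filtered plant height, image-moment centroid) and the relative
    height of the plant centroid (RHC), reduces the silhouette to leaf line
    segments via skeletonization and a deterministic progressive Hough
    transform, fits the logarithmic vertical leaf-angle distribution model
    A = a*ln(RH+1) + b, and computes the comparison shape descriptors GPAR
    (green projected area ratio) and PAR (perimeter-area ratio). Includes a
    synthetic plant-image generator with full ground truth for validation,
    and the downstream statistics used to relate traits to growth status
    (one-way ANOVA with Tukey HSD, multivariate linear regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Visualization, Phenotype
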