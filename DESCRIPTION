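Package: seedgeom
Title: Geometric Models and Silhouette Morphometry for Vitaceae Seeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for describing and classifying seed silhouettes with
    algebraic planar curve models. Implements a family of closed curves
    (ellipses, superellipses, lenses, water drops and heart curves) built
    from factored ellipse equations, renders them as polygons and binary
    masks, extracts orientation-normalized silhouettes from grayscale seed
    images, and quantifies similarity between a silhouette and a model with
    the J index (percentage ratio of shared to total surface area under
    optimal superposition). Seeds are assigned to ten morphological groups
    described for the Vitaceae; the published model parameters, group
    membership and species tables are packaged as queryable registries. A
    synthetic-silhouette generator with controlled radial deformation
    supports validation without real images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
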