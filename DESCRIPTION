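Package: htcolony
Title: Label-Free Pluripotency Assessment of Stem-Cell Colonies from
    Refractive-Index Tomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for 3D refractive-index (RI) tomograms of live
    human pluripotent stem-cell colonies acquired by holotomography.
    Segments colony footprints and occupancy volumes by RI thresholding and
    morphological closing, tiles colonies into fixed-size patches, and
    classifies each patch as undifferentiated versus differentiating with a
    bottleneck-attention residual network implemented natively in R,
    including training (SGD with Nesterov momentum and cosine annealing),
    checkpoint selection, and Grad-CAM saliency. Patch probabilities are
    aggregated into colony-level calls, and a 31-property morphometric
    profile (thickness, curvature, dry mass, lipid and gap content, shape
    and spatial-moment descriptors) is extracted per colony for downstream
    Leiden clustering, UMAP embedding, effect-size and correlation
    analysis. A phantom generator produces synthetic tomograms with ground
    truth so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
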