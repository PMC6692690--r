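Package: ductlayers
Title: Duct-Centric Structure Features and Hierarchical Diagnosis of Breast Biopsy Tissue Maps
Version: 0.1.0
Authors@R: person("ductlayers", "developers", email = "ductlayers@example.org", role = c("aut", "cre"))
Description: Post-segmentation analysis of breast-biopsy regions of interest
    given a pixel-level tissue-label map over eight clinical tissue classes.
    Partitions a region into superpixels, assigns majority tissue labels,
    detects ducts (and duct groups or tumour masses) as connected components
    of epithelium, secretion and necrosis superpixels, peels five inner and
    five outer one-superpixel-thick layers around each duct, and summarises
    each region as an 80-dimensional layered tissue histogram ("structure
    feature") plus a 44-dimensional tissue frequency and co-occurrence
    feature. Includes the matching evaluation protocol (balanced subsampling,
    per-fold PCA, third-degree polynomial-kernel support vector machine,
    leave-one-out cross-validation, repeated subsampling) for the three
    hierarchical diagnostic tasks (invasive vs noninvasive, atypia+DCIS vs
    benign, DCIS vs atypia), and a synthetic label-map generator with
    category-specific ductal morphology for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
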