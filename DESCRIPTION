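Package: spotcna
Title: Spatial Copy Number Alteration Inference for Dense Spot-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers copy number alterations (CNAs) and malignant clones from
    sparse, high-density spot-based spatial transcriptomics data such as
    Slide-seq. Raw bead counts are transformed into reference-centred log
    expression, smoothed along each chromosome with a pyramidal weighted
    moving average, and aggregated into spatio-molecular bins by Ward
    clustering of a combined spatial/expression pseudo-distance. Bin-level
    CNA scores are clustered into clones with silhouette-based model
    selection, and clusters are compared by negative binomial differential
    expression and chromosome-arm Spearman concordance. Includes an in
    silico bead simulator (Gaussian-kernel aggregation of cell profiles with
    implanted arm-level CNAs and binomial downsampling) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    cluster,
    data.table,
    ggplot2,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
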