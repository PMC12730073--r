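Package: radrobust
Title: Cross-Software Robustness Screening for Radiomic Features
Version: 0.1.0
Authors@R:
    person("Radiomics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-stage workflow for assessing the robustness of radiomic
    features within and across extraction platforms. Screens features for
    intra-software repeatability with the intraclass correlation ICC(A,1) on
    repeated segmentations, groups redundant features by agglomerative
    hierarchical clustering under five distance metrics and five linkage
    rules with consensus selection of the number of clusters, gates
    cross-platform configurations by the Adjusted Rand Index, and ranks
    features by a Composite Index combining inter-platform correlation,
    Kolmogorov-Smirnov distributional distance and mean-fractional-ratio
    scale bias, selecting per-cluster winner features and a quality-filtered
    non-redundant final set. Includes a synthetic-data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    cluster,
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
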