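Package: GECluster
Title: Protein Complex Prediction from Dynamic and GO-Weighted PPI Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs condition-specific (dynamic) protein-protein
    interaction networks from time-course gene expression data, augments
    them with edges weighted by shared GO-slim annotations (combined
    networks), and detects protein complexes with a seed-node-expansion
    algorithm driven by FS-Weight functional similarity and a cluster
    density criterion. Includes complex-level evaluation (matching score,
    recall, precision, F1), network summary statistics, cross-condition
    complex-evolution mapping with core/attachment composition reports,
    and a synthetic benchmark generator with planted complexes so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, Clustering, SystemsBiology
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'io.R'
    'dynamic.R'
    'combined.R'
    'similarity.R'
    'gecluster.R'
    'evaluation.R'
    'evolution.R'
    'synthetic.R'
    'pipeline.R'
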