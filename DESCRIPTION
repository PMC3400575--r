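Package: tregnet
Title: Transcriptional Regulatory Network Inference and Integration Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for nominating candidate disease
    regulators from gene-expression compendia. Implements mutual-information
    estimation with B-spline soft discretization, context-likelihood (CLR)
    background correction, data-processing-inequality (ARACNE-style) edge
    pruning, two-group differential expression with Benjamini-Hochberg
    control and median probe-set collapsing, sparse factor-analysis
    biclustering, L1-regularized signed regulator selection per bicluster,
    maximum-likelihood estimation of domain-domain interaction
    probabilities, susceptibility-locus overlap of network neighborhoods,
    and a synthetic-data generator with planted structure for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    glmnet,
    igraph,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
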