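Package: klsnet
Title: Individualized Metabolic Brain Networks from Divergence-Based Similarity
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Constructs individualized metabolic brain connectomes from
    parcellated volumetric uptake images. Per-region voxel intensity
    distributions are estimated by Gaussian kernel density estimation and
    every region pair is connected by the Kullback-Leibler divergence based
    similarity (KLS), yielding a symmetric weighted adjacency matrix per
    subject. The package sweeps sparsity thresholds over each network,
    computes weighted global and nodal graph metrics normalized against
    degree-preserving random nulls, compares groups edgewise and metric-wise
    with covariate adjustment and false discovery rate control, and predicts
    a continuous clinical outcome from discriminating connections with
    L2-regularized L2-loss support vector regression under leave-one-out
    cross-validation and permutation inference. A synthetic-cohort simulator
    with planted group effects and outcome coupling makes every stage
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Regression, PositronEmissionTomography
RoxygenNote: 7.3.3
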