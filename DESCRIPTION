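Package: ErrPOT
Title: Transferable Single-Trial Error-Related Potential Decoding via
    Regularized Optimal Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cross-subject decoding of error-related potentials
    (ErrPs) from feedback-locked EEG epochs. Provides a synthetic
    multi-subject cohort generator with controllable per-subject covariate
    shifts, a preprocessing chain (equiripple FIR low-pass, surface
    Laplacian, baseline correction, decimation) producing low-frequency
    amplitude feature vectors, entropy- and group-sparsity-regularized
    discrete optimal transport with Sinkhorn scaling and barycentric
    mapping for domain adaptation, leave-one-subject-out classification
    with a random forest and comparison classifiers, and nonparametric
    event-related-potential statistics (per-timepoint Kruskal-Wallis,
    exact Wilcoxon signed-rank).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    boot,
    MASS,
    rpart,
    randomForest,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
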