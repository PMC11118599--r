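Package: dvgs
Title: Data Valuation with Gradient Similarity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns each source sample a data value equal to its average
    gradient cosine similarity to target-batch gradients along a stochastic
    gradient descent trajectory (DVGS), for both supervised (classification)
    and unsupervised (autoencoder reconstruction) tasks. Includes baseline
    valuation methods (random, leave-one-out, truncated Monte-Carlo Data
    Shapley), label-flip and Gaussian feature-noise corruption generators
    with retained ground truth, and the matching evaluation statistics:
    corruption-discovery AUROC, noise-rate Spearman correlation,
    filter-and-retrain performance curves, and the average Pearson
    correlation (APC) replicate-quality metric for L1000-style expression
    data. Seeded synthetic-data generators provide separable labeled tables
    and replicate-structured expression sets so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, MachineLearning, QualityControl, Transcriptomics
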