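Package: sparseMET
Title: Sparse Testing Designs and Multi-Trait Genomic Prediction for
    Multi-Environment Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic sparse testing in plant breeding
    multi-environment trials. Provides four allocation strategies for
    assigning breeding lines to environments (from fully overlapped
    subsets to incomplete-block constructions balancing pairwise line
    concurrence), a VanRaden genomic relationship matrix builder, a
    first-stage mixed-model pipeline producing weighted BLUEs from
    incomplete-block field data, a multi-trait Bayesian GBLUP model with
    genotype-by-environment interaction fitted by Gibbs sampling, a
    cross-validation harness reporting Pearson correlation and
    normalized RMSE for untested lines in tested environments, a
    cost-benefit calculator for sparse versus fully replicated designs,
    and a synthetic-data generator with known truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
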