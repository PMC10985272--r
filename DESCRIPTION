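Package: heteroDTU
Title: Differential Transcript Usage Detection in Heterogeneous Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differential transcript usage (DTU) in case/control
    RNA-seq cohorts where the case group may be genetically heterogeneous.
    Per transcript, isoform-fraction distributions of the case group are
    partitioned into subgroups via Gaussian kernel density estimation, the
    matched tails of case and control groups are compared with Mann-Whitney
    U tests, and calls are thresholded against an empirical null of minimal
    U-statistic p-values built by repeatedly splitting the control group.
    Confounded calls are vetoed with a depth-one random-forest permutation
    importance test, and case samples are clustered into spliceotype
    subgroups from the binary DTU event matrix. Includes a dominance-swap
    DTU cohort simulator, pseudo inferential replicate generation with
    majority-vote call combination, and leave-one-out cross-validated
    fitting of the bandwidth and threshold hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, BiocGenerics, S4Vectors, ape, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
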