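Package: isml
Title: Integrated Statistical and Machine Learning Selection of Classifier Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies, ranks and iteratively refines small sets of classifier
    genes from multi-class gene-expression matrices. Implements spike-in based
    pre-processing, random-variance (moderated) t/F tests with multivariate
    permutation control of the number of false positives, decision-tree based
    classifier-gene selection with a weight-of-significance ranking, backward
    elimination refinement under multi-class SVM and k-means evaluators, nested
    stratified cross-validation, and a synthetic-data generator with planted
    discriminative genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
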