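Package: alscreen
Title: Simulation Framework for AI-Aided Abstract Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study active-learning prioritisation of abstracts in
    systematic-review screening. Provides a synthetic labeled-corpus
    generator with controllable size, prevalence and class separability;
    prevalence and frequency manipulation of labeled collections; an
    active-learning simulation engine with interchangeable classifiers
    (logistic regression, naive Bayes, support vector machine, random
    forest, two-hidden-layer neural network) and feature extractors
    (TF-IDF plus a plug-in interface for embedding models); the screening
    performance metrics screening cost, false-positive rate, relevant
    records found and work saved over sampling; heuristic stopping rules
    (consecutive-irrelevant, time-based, key-study, combined, breakout);
    factorial experiment orchestration with replication-level summaries;
    and practical stopping-rule recommendations with workload-saving
    projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    glmnet,
    e1071,
    ranger,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
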