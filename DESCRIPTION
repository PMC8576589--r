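Package: kgembed
Title: Confidence-Weighted Knowledge Graph Embeddings for Adverse Drug
    Event Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Representation learning for noisy, literature-derived biomedical
    knowledge graphs. Implements DeepWalk-style random-walk embeddings trained
    with skip-gram negative sampling and TransE translation embeddings trained
    with a margin-ranking loss, together with confidence-weighted variants that
    bias random walks (softmax over max-normalized triplet confidence scores)
    and reweight the TransE energy by triplet confidence. Includes readers and
    writers for SemMedDB-style triplet tables and word2vec-format embedding
    files, downstream adverse-drug-event and polypharmacy classification
    pipelines (logistic regression, k-nearest neighbours, random forest;
    leave-one-out, stratified 5-fold and cross-dataset validation; F1, AUC,
    AUPRC and average precision at 50), and a synthetic noisy knowledge-graph
    generator with planted drug-disease structure and truth-correlated
    confidence scores for end-to-end evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    ranger,
    class
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
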