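Package: otrepo
Title: Drug Repositioning from Fused Drug Networks with an
    Optimal-Transport Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-based drug repositioning. Nine heterogeneous drug
    networks (chemical-structure, side-effect, target-sequence, gene-ontology
    and therapeutic-class similarities, drug-drug interactions, and
    drug-gene, drug-side-effect and drug-disease bipartite graphs) are
    embedded via random-walk co-occurrence and positive pointwise mutual
    information, fused into a low-dimensional drug representation with a
    multimodal autoencoder, and fed to a variational autoencoder trained
    with an entropic optimal-transport (Wasserstein) composite loss that
    reconstructs disease-drug association rows and ranks repositioning
    candidates. Includes a synthetic benchmark generator with planted
    cluster structure and the standard link-prediction evaluation protocol
    (80:20 split, five-fold cross-validation, AUROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
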