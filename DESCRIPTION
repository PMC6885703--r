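Package: mhcdecon
Title: Deconvolution of Multi-Allele MHC Peptidomes with Pan-Specific Neural Networks
Version: 0.1.0
Authors@R: person("Maintainer", "mhcdecon", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-supervised deconvolution of poly-specific (multi-allele) MHC
    eluted-ligand datasets. A pan-specific one-hidden-layer neural network with
    two output neurons (binding affinity and eluted-ligand likelihood) is
    pre-trained on single-allele data, then multi-allele ligands are iteratively
    annotated to one MHC molecule of their cell line via z-score rescaled
    prediction values and merged back into training. Includes binding-core
    enumeration and BLOSUM encoding, common-motif cross-validation partitioning,
    random-natural negative enrichment, per-allele motif construction and
    comparison, and evaluation statistics (AUC, AUC0.1, PPV, Frank), together
    with a synthetic-world generator for fully self-contained benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
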