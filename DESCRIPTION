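Package: proveanr
Title: Protein Variation Effect Prediction from Alignment Score Changes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the functional effect (deleterious versus neutral) of
    protein sequence variations - single and multiple amino acid
    substitutions, in-frame insertions and deletions - from the change in
    semi-global (free end-gap) alignment score that a variant induces
    against a set of homologous supporting sequences. Homologs are
    deduplicated by greedy identity clustering, delta scores are averaged
    within and then across clusters so each cluster is weighted equally,
    and the averaged delta score is thresholded to call a variant
    deleterious. Includes a saturation scan over all single-residue
    variants, evaluation utilities (balanced accuracy, ROC/AUC, balanced
    separation threshold selection, parameter-grid sweeps), a synthetic
    homolog-family generator for download-free benchmarking, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
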