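Package: cacofold
Title: Covariation-Constrained Prediction of Conserved RNA Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts a conserved RNA consensus structure from a multiple
    sequence alignment by combining positive and negative evolutionary
    information. Column pairs that significantly covary (APC-corrected
    G-test calibrated against a phylogenetic null model) are forced into
    the structure; variable pairs without covariation are forbidden. A
    cascade of constrained probabilistic grammars (RBG for the main nested
    fold, G6X for alternative layers) incorporates every significantly
    covarying pair, including pseudoknots, triplets and alternative
    helices, which are then filtered, merged and annotated. Includes a
    synthetic-alignment generator with planted compensatory substitutions
    for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
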