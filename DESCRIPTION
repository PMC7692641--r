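Package: pepstack
Title: Three-Class Anticancer and Antimicrobial Peptide Classification
    with Gapped n-Grams and Stacked Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies peptides into anticancer (ACP), antimicrobial (AMP)
    and background (non-ACP/non-AMP) classes. Peptides are decomposed into
    overlapping 5-mers, each encoded as binary occurrences of continuous and
    gapped n-grams (n = 1-3); informative n-grams are selected with an exact
    permutation test (QuiPT) on every pairwise class contrast, a first random
    forest scores the 5-mers, and a second forest classifies whole peptides
    from summary statistics of their 5-mer class probabilities. Includes
    physicochemical profiling (net charge, Kyte-Doolittle hydropathy, residue
    composition), length-stratified cross-validation, multi-class evaluation
    (Hand-Till AU1U, Cohen's kappa, MCC), a synthetic peptide generator for
    offline testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    optparse,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
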