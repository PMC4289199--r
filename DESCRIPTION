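Package: recspot
Title: Recombination Hot/Cold-Spot Classification from Pseudo Nucleic Acid
    Composition with SVM-RFE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encodes DNA sequences as pseudo nucleic acid composition
    (PseNAC) feature vectors: mononucleotide through 5-mer frequency tiers
    plus pseudo dinucleotide composition (PseDNC) sequence-order coupling
    factors built on six normalized dinucleotide structural properties
    (twist, tilt, roll, shift, slide, rise). Ranks features by recursive
    feature elimination with a linear-kernel support vector machine
    (SVM-RFE), with a two-class F-score ranker as baseline; selects the
    regularization parameter C and the number of retained top features by
    grid search under leave-one-out (jackknife) cross-validation; and
    reports sensitivity, specificity, accuracy, Matthews correlation
    coefficient, ROC curves and AUC. Includes a synthetic-sequence
    generator with planted dinucleotide-composition signal for end-to-end
    validation, and a command-line interface over the same functions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
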