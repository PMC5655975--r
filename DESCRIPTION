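Package: bpsfinder
Title: Branch Point Sequence Prediction in Human Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Heuristic prediction of the branch point sequence (BPS) in human
    introns. Locates the polypyrimidine tract under rule-based criteria,
    derives the AG exclusion zone (AGEZ) and the shortened AGEZ that bounds
    the branch-point search, and scores every candidate heptamer with a
    family of measures combining a position-specific scoring matrix, the
    co-folding binding energy between the candidate and the U2 snRNA GUAGUA
    motif, and the branch-site nucleotide preference. Includes an evaluation
    harness with Hamming-distance and PWM-over-AGEZ baselines, a deterministic
    synthetic-intron generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
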