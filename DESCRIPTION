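Package: repwm
Title: Iterative Refinement of Mono- and Dinucleotide Position Weight Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery of putative transcription-factor binding sites on
    TSS-aligned promoter sequences by iterative position-weight-matrix (PWM)
    refinement. Builds background-corrected log-odds PWMs in mononucleotide
    (4 x L) and dinucleotide (16 x (L-1)) form from aligned binding sites,
    detects promoter regions with over-represented matrix hits via positional
    z-score profiles over a grid of matching cut-offs, and iteratively regrows
    the matrix from hits in the detected functional window, optimising motif
    length and cut-off against the Matthews correlation coefficient. Includes
    a seeded synthetic-benchmark generator (planted motifs and aligned-site
    embedding tests with background-reshuffled replicates) and tolerance-based
    evaluation metrics (precision, recall, Matthews correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
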