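Package: ncrates
Title: Conservative and Non-Conservative Substitution Rates in Protein-Coding
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the evolutionary parameter lambda = dNC/dC, the rate
    ratio of non-conservative (likely protein-destabilizing) to conservative
    amino-acid substitutions, from pairs of orthologous coding sequences.
    Provides an extended pairwise maximum-likelihood codon model with
    parameters for divergence time, transition/transversion bias, selection
    on amino-acid changes and selection against destabilizing changes, and an
    independent extended Nei-Gojobori-style count estimator with mutational
    pathway averaging and Jukes-Cantor multiple-hit correction. Includes a
    stability-based classification of single-nucleotide-neighbor amino-acid
    pairs, derivation of classifications from predicted folding free-energy
    changes, Blosum62 consistency validation, codon-alignment construction by
    back-translation with curation filters, sequence and network simulators
    with known ground truth, and protein-interaction-network statistics
    (hubs, bottlenecks, re-wiring consensus, rank-sum/Fisher tests and
    standardized mean differences).
License: MIT + file LICENSE
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
    igraph,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
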