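Package: zfscreen
Title: Zinc-Finger Binding-Site Prediction, Genome Scanning and Target
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for nominating direct targets of C2H2 zinc-finger
    transcription factors. Detects C2H2 zinc-finger domains in a protein,
    predicts a DNA-binding position weight matrix under the canonical
    binding model via a user-replaceable recognition-code table, scans
    DNA (gene flanks or whole contigs) for motif occurrences with
    log-odds scores and exact p-values from the null score distribution,
    and intersects flank hits with a differential-expression table to
    nominate candidate direct targets. Companion modules compute
    sliding-window nucleotide diversity and Hudson's Fst between two
    populations with top-quantile outlier calling, relative qPCR
    expression by the 2^-ddCt method with significance tests,
    neighbor-joining phylogenies with bootstrap support, and seeded
    synthetic-data generators (toy genome with planted binding sites,
    differential-expression tables, two-population haplotypes, Ct
    tables) so every stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
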