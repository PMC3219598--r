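Package: retrochar
Title: Characterization of L1 Endonuclease-Mediated De Novo Retroelement Insertions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize de novo Alu, LINE-1 and poly(T) insertions
    created by L1 endonuclease-dependent target-primed reverse transcription
    (TPRT). Given reference and mutant allele sequences the package resolves
    breakpoints and target-site duplications (TSDs), measures poly(A)/poly(T)
    tails, infers insert orientation, classifies the inserted element into Alu
    subfamilies or L1 subsets, detects 5'-inverted (twin-primed) L1 bodies,
    scores integration sites against the L1 endonuclease cleavage consensus,
    finds recurrently used sites and insertion clusters, emits HGVS-style
    mutation names, and types the transcript-level splicing consequence. A
    TPRT simulator with full ground truth and a reconstructed 18-case NF1
    fixture set allow every stage to be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
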