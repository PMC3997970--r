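Package: rsrcode
Title: Rank-Specific Recognition Codes for Zinc Finger Binding Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the DNA-binding preferences of C2H2 zinc
    finger domains as rank-specific recognition (RSR) codes: derivation of a
    1-to-64 triplet ranking from electrophoretic mobility shift assay (EMSA)
    count tables, threshold and base-composition summaries, rank-correlation
    comparisons between proteins, exact and degenerate k-mer occurrence
    scanning of genomes (including paired zinc finger nuclease half-site
    searches with a spacer), composite binding-site construction for
    multi-finger design strategies, and synthetic-data generators (EMSA probe
    cassettes, noisy count tables with known ground truth, genomes with
    planted motifs) for testing the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    IRanges,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
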