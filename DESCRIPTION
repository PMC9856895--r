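Package: riplab
Title: Control-Calibrated RIP-Seq Target Calling and Courtship-Memory
    Statistics for Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studies of the Drosophila CPEB protein
    Orb2 and long-term memory. Calls protein-coding mRNA targets from
    three-sample RIP-seq count tables (Input, IP, mock IP) using
    counts-per-million normalization, dual enrichment ratios and thresholds
    calibrated on positive-control transcripts; computes courtship and
    learning indices from bout logs and compares groups with sampled
    randomization tests; counts canonical and noncanonical cytoplasmic
    polyadenylation elements (CPEs) in 3'UTR isoforms and simulates
    interval deletions; quantifies serial-dilution immunoblots, relative
    qPCR expression (delta-delta-Ct) and immunoprecipitation yield; and
    tests overlap and over-representation against published gene sets.
    Every pipeline input can be generated synthetically with recorded
    ground truth from a seeded generator.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
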