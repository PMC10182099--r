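Package: resectr
Title: Genome-Wide Mapping of DNA End Resection, Re-Synthesis and Gene
    Conversion from Paired-End Sequencing Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the repair of a site-specific DNA
    double-strand break from paired-end short-read sequencing of a cell
    population. Implements coverage-based estimators of 5'-3' end
    resection (short-range decline, long-range rate from the 0.5-coverage
    crossing, maximum extent at a 0.9 cutoff), DNA re-synthesis rates from
    trend lines at fixed distances from the break, per-polymorphism gene
    conversion fractions with a repair-efficiency correction, and
    gene-conversion tract boundary mapping from inter-chromosomal
    discordant read pairs. Ships a synthetic recipient/donor reference
    genome generator with in-silico restriction digestion, a cell
    population simulator with single-strand-aware paired-end read
    emission (double-stranded fragments only, as in tagmentation
    libraries), and an exact-match (0-mismatch) read mapper, so the whole
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
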