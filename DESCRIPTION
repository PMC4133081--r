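Package: metcomp
Title: Comparative Genomics of Entomopathogenic Fungi: Assembly Statistics,
    RIP Quantitation, Orthology Classes and Effector Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy toolkit for the comparative-genomics analysis layer of
    three-species fungal genome studies (Metarhizium-style). Computes assembly
    summary statistics (N50 rank and length, GC content, gene density, repeat
    coverage), genome-wide dinucleotide and repeat-induced point mutation (RIP)
    indices, deRIP consensus reconstruction of repeat-family alignments with
    per-family RIP-like mutation classification and dominance scores,
    ortholog-group classification into shared, divergent and expanded sets,
    candidate secreted-effector screening (motif scanning, molecular weight,
    isoelectric point, secretion joins), mating-type (MAT) thallism typing, and
    a fully seeded synthetic three-species data generator with planted ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
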