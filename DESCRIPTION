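Package: regbash
Title: Consequence Classification and Curation of Gene-Regulatory Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Categorizes point mutations and small indels against a
    transcript-centric genome annotation (with conservative resolution of
    overlapping features), encodes literature-curation rules for candidate
    cis-regulatory alleles (exclusion criteria, core-promoter/enhancer/
    promoter assignment, distance to the transcription start site, inferred
    native activity), and computes census-style summary statistics over
    alleles and reporter-bashing studies (category breakdowns, distance
    distributions with bootstrap confidence intervals, per-technique
    throughput). Ships a synthetic genome, allele and study-table simulator
    with known ground truth so the whole pipeline is testable end to end
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
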