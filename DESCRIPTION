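Package: rnatails
Title: Non-Templated 3' Tail Calling and Decay Kinetics for Small RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the 3' ends of small RNAs from 3'-end
    sequencing reads. Decomposes each read into its templated body (mature
    sequence plus genomically encoded downstream extension) and a
    non-templated tail, classifies tails (mono-/oligo-adenylation,
    mono-/oligo-uridylation, U-then-A), aggregates per-reference 3'-end
    profiles, compares conditions, quantifies guide/passenger strand
    asymmetry, and fits first-order decay kinetics from transcription-shutoff
    time courses. Includes a synthetic read generator with per-read ground
    truth for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
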