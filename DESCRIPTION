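Package: secretopep
Title: Neuropeptide-Style Processing Analysis of an Algal Mating Secretome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a secretome carries the hallmarks of
    classical neuropeptide-precursor processing. Scans signal-peptide-bearing
    soluble proteins for prohormone convertase ((K/R)Xn(K/R)) and furin
    (RX(K/R)R) cleavage motifs and for C-terminal amidation signatures,
    enumerates the peptide products implied by cleavage, carboxypeptidase
    B-like trimming and peptidylglycine alpha-amidating monooxygenase action,
    merges replicate label-free spectral-count runs with a presence filter and
    equal-total normalization, classifies membrane topology from
    signal-peptide and transmembrane-helix annotations, and infers
    endoproteolytic cleavage of secreted proteins from SDS-PAGE gel-slice
    resolved tryptic-peptide evidence. A seeded synthetic-data generator
    plants motifs, presence patterns and gel fragments with recorded ground
    truth so every stage is verifiable without external downloads.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
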