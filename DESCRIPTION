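Package: snapanel
Title: Design and Decoding of Multiplex SNaPshot Minisequencing Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing multiplex PCR and single-base-extension
    (SNaPshot minisequencing) genotyping panels for biallelic SNVs, and for
    decoding capillary-electrophoresis peak tables into genotype calls.
    Includes melting-temperature estimation, primer secondary-structure and
    cross-dimer screening, in-silico PCR, dye-aware extension-primer length
    staggering with neutral 5' tails, electropherogram simulation, an
    independent panel-constraint checker, and a PCR-RFLP differential-digest
    predictor. Ships the published 12-plex BCL11A and 16-plex HBS1L-MYB
    fetal-haemoglobin modifier panels as packaged fixtures together with a
    toy-genome generator for network-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
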