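Package: foldbackr
Title: Simulation and Detection of Hairpin-Mediated Foldback Inversion
    Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gross chromosomal rearrangements (GCRs)
    mediated by single-stranded DNA hairpins in a yeast-style
    counter-selection assay. Generates annotated toy assay genomes with
    planted hairpin-forming inverted repeats, applies foldback-inversion
    and other GCR events with their secondary resolutions, simulates
    paired-end reads, calls rearrangement junctions from discordant read
    pairs with read-depth and span-depth profiles, classifies GCR
    structures and foldback resolution products, and implements
    fluctuation-analysis rate estimation with bootstrap proportion
    confidence intervals and error-propagated subtype rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
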