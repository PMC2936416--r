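Package: sidmap
Title: Selected Interacting Domains from Yeast Two-Hybrid Fragment Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of yeast two-hybrid screens that use single-chain
    antibodies (scFv) as bait against random-primed cDNA fragment libraries.
    Maps retained prey fragments onto reference open reading frames in
    residue coordinates, classifies reading frame, clusters overlapping
    fragments and computes the Selected Interacting Domain (SID) of each
    cluster, ranks prey genes with an e-value-like confidence score under a
    competition-for-bait null model (PBS categories A-F), narrows binding
    regions by tiling deconvolution of gap-repair calls, and compares SIDs
    across homologues by global alignment. Includes a synthetic screen
    generator emulating random-primed fragment libraries so that every stage
    is testable without wet-lab data.
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
    withr
Config/testthat/edition: 3
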