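Package: deplink
Title: Diethyl Phosphate Adducts and Zero-Length Isopeptide Cross-Links
    in Peptide Tandem Mass Spectra
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identification of organophosphate-derived diethyl phosphate
    (+136.0289 Da) adducts and zero-length glutamate-lysine isopeptide
    cross-links (-18.0106 Da bridge) in peptide MS/MS peak lists.
    Provides monoisotopic mass arithmetic, immonium-derived signature
    ions, theoretical b/y fragment generation for linear and
    cross-linked peptides, in-silico tryptic digestion, precursor-mass
    candidate enumeration, peak matching with a multi-criterion
    acceptance procedure including an alternative-explanation
    false-positive screen, and a seeded generator of ground-truth
    synthetic Orbitrap-like spectra for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
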