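Package: tcrdock
Title: Interface Analysis and Docking Topology of TCR-pMHC Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of T cell receptor (TCR) recognition of
    peptide-MHC, built around atypical binding modes such as reversed-polarity
    and end-to-side docking. Parses deposited complex coordinates (PDB/mmCIF),
    annotates TCR variable domains on the IMGT unique numbering scheme,
    decomposes interface buried surface area by CDR loop and framework region
    using a deterministic Shrake-Rupley surface, types cross-interface atomic
    contacts (hydrogen bonds, salt bridges, van der Waals), classifies docking
    topology from Valpha/Vbeta centroid geometry, fits steady-state 1:1 surface
    plasmon resonance binding isotherms with categorical mutant-effect calls,
    normalizes Luminex single-antigen HLA bead panels, and scores interface
    sequence conservation. Includes synthetic-data generators so every stage is
    testable without downloading deposited structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
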