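Package: dnathread
Title: Template-Based Prediction of DNA-Binding Proteins and Their Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether a protein sequence binds DNA by threading the
    query onto a library of known protein-DNA complex structures, scoring
    each threaded complex with a distance-scaled finite ideal-gas
    reference-state (DFIRE-type) statistical potential restricted to
    protein main-chain atoms, and applying a two-threshold decision rule
    (fold-recognition match probability plus binding energy). For accepted
    predictions it emits the modeled complex in PDB format and the
    predicted DNA-binding residues (heavy atoms within 4.5 Angstrom of a
    DNA base). Includes the template-library construction filters,
    leave-one-out benchmarking with sequence-identity exclusion, MCC-based
    threshold optimization, an HHR (HHsearch/HHblits) report parser with a
    Needleman-Wunsch fallback aligner, and a deterministic synthetic
    fixture generator for idealized protein-DNA complexes and decoys.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
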