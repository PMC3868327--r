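Package: ptmsurf
Title: Structure-Based Mapping and Enrichment Analysis of Protein
    Post-Translational Modification Sites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps curated post-translational modification (PTM) sites onto
    three-dimensional protein models and quantifies their relationship to
    paralog sequence variation. Provides a deterministic Shrake-Rupley
    solvent-accessibility engine with buried/exposed classification,
    minimum heavy-atom-distance proximity analysis with a configurable
    sphere-radius cutoff, partitioning of a protein surface into a
    variant-enriched variable face and a conserved face, side-chain
    compatibility rules for nine modification chemistries with detection of
    isoform-specific modifiability, citation-based evidence filtering, and
    a permutation test (with exact enumeration on small instances) of PTM
    enrichment near surface clusters of sequence variants. Includes
    synthetic-data generators with known ground truth for every stage.
    Developed around the eEF1A1/eEF1A2 elongation-factor paralog pair.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
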