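Package: phagefunnel
Title: NGS-Guided Funnel Screening of Phage-Display scFv Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes per-cycle deep-sequencing data from phage-display
    biopanning of single-chain variable fragment (scFv) antibody libraries
    into a ranked list of candidate target-specific binders.  Implements a
    six-step "funnel": counts-per-million normalization, a positive-delta
    inter-cycle enrichment filter, an open-reading-frame validity cascade
    (framework-1 consensus, stop codons, framework-4 consensus) that removes
    propagation-advantage false positives, aggregation of synonymous clones,
    and a persistent cross-screen database of target-unrelated clones.
    Includes breakpoint-cycle diagnostics based on clonal entropy and
    top-clone saturation, and a seeded multi-cycle biopanning simulator with
    ground-truth labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
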