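Package: nuprtools
Title: Structural and Sequence Characterization of NUPR1-Like Helix-Loop-Helix Chromatin Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for small, intrinsically disordered
    helix-loop-helix chromatin proteins of the NUPR1/HMGA type. Provides PDB
    structure input/output with atom-name dialect normalization; consensus
    quality assessment of candidate structural models against a negative
    control (Kabsch superposition, C-alpha RMSD and shuffle-null Z-score
    matrices, aggregate statistics and ranking, Ramachandran summaries);
    secondary-structure and beta/gamma-turn assignment with solvent
    accessibility; protein-DNA interface analysis with explicit geometric
    cutoffs (salt bridges, hydrogen bonds, electrostatic and hydrophobic
    contacts), in-silico mutagenesis and interaction rewiring; rigid-body
    docking onto ideal B-DNA with minor-groove occupancy assignment;
    conformational-ensemble analytics (per-residue RMSF, pairwise frame RMSD,
    helix persistence, disorder consensus); and sequence-level scans for
    NLS/NES/AT-hook motifs, hydropathy and physicochemical profiles, alignment
    identity/conservation, and consensus scoring of post-translational
    modification site predictions. Includes seeded synthetic-data generators
    (ideal helices, fiber-model B-DNA duplexes, conformational ensembles with
    known order/disorder schedules, predictor tables, motif-embedded
    sequences) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
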