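Package: InterfaceContacts
Title: Typed Protein Interface Contact Maps, Degenerate Motif Scanning,
    and Binding-Site Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing protein-protein interfaces at residue
    resolution using distance-cutoff interaction typing (hydrophobic,
    ionic, hydrogen bond, cation-pi) on heavy-atom crystal structures,
    with protein-DNA contact flagging, cross-structure comparative
    contact maps, derivation and scanning of degenerate consensus
    sequence motifs, a registry of peptide deletion constructs with
    experimental binding outcomes, and alignment-based transfer of
    interface contacts onto candidate peptides to propose binding
    sites. Includes generators for synthetic structures and sequence
    databases with planted ground truth, and an end-to-end pipeline
    driver. Motivated by the interaction of the Arabidopsis orphan
    protein QQS with the NF-YC subunit of the CCAAT-binding NF-Y
    transcription factor at the interfaces occupied by the NF-YB
    N-terminal region.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
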