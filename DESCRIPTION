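Package: polsuper
Title: Hierarchical Maximum-Likelihood Superposition of Viral Polymerase Structures
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for superposing families of nucleic-acid polymerase structures
    into a single common coordinate frame.  Residue equivalences are established by
    multiple sequence alignment (built-in progressive aligner or a curated CLUSTAL
    file), structures are fitted by an iterative maximum-likelihood multiple
    superposition that estimates a per-position coordinate variance and
    down-weights divergent regions, and whole families are chained through an
    alignment tree in which each superposition set inherits its orientation from
    its parent via a shared seed structure.  Includes fixed-column PDB reading and
    writing with the project's file conventions, pseudo B-factor flexibility maps
    (8*pi^2 times positional variance), pseudoatom-anchored region selection,
    catalytic-aspartate DD distance surveys, metal-ion pooling and binding-site
    assignment, and generators for ground-truth synthetic test structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
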