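Package: structkit
Title: Structural Bioinformatics Toolkit for PDB Structures, Sequences and
    Ensembles
Version: 1.0.0
Authors@R:
    person("structkit", "developers", email = "structkit@example.org",
           role = c("aut", "cre"))
Description: A single-language toolkit for everyday structural bioinformatics:
    a Structure/Chain/Residue/Atom data model, a filter-based fixed-column PDB
    reader with a fast coordinate-swap path for multi-model trajectories,
    FASTA and sequence-profile utilities, geometric calculators (Kabsch
    superposition and crmsd, backbone phi/psi dihedrals with Ramachandran
    classes, residue contact maps, aromatic ring reference frames and stacking
    descriptors), agglomerative hierarchical clustering of structure ensembles
    with medoid extraction, pairwise global sequence alignment, a "one
    task-one app" command-line suite, and a deterministic synthetic-fixture
    generator used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
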