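Package: gpcrcore
Title: Core-Region Composition Profiling of GPCR Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Motif-anchored analysis of G-protein-coupled receptor (GPCR)
    protein families. Extracts the core region between the most N-terminal
    N-linked glycosylation sequon (NxS/T/C) and the NPxxY motif at the end of
    transmembrane helix 7, applies a 270-401 residue length filter, and
    profiles families by amino-acid composition, Kyte-Doolittle
    hydropathy-weighted difference scores, and anchored positional residue
    distributions. Also provides alignment-column conservation statistics
    (sequence-logo data), pairwise global-alignment identity, and a seeded
    synthetic-family generator for validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
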