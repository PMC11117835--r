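Package: ubnin
Title: Exact Encoding of Binary Brain Networks as Unique Identification Numbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes a binary, undirected brain-network adjacency matrix into a
    single exact number (a UBNIN, Unique Brain Network Identification Number)
    and decodes that number back to the original matrix without loss. The
    modified variant places the column code of a cohort's maximally occurring
    principal node (the hub most often of highest degree) in the integer part
    and packs the remaining columns into a terminating dyadic fraction. All
    codec arithmetic is exact rational (no binary floating point), so the full
    fractional expansion is preserved and the matrix-to-number map is injective
    for a fixed node count and principal node. Includes cohort-level batch
    encoding, a seeded random-matrix generator, a collision (uniqueness)
    experiment, readers and writers for adjacency and edge-list files, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
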