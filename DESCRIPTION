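Package: minorintrons
Title: Classification, Conservation and Ancestral Reconstruction of Minor
    Spliceosomal Introns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for surveying minor (U12-type) spliceosomal introns across
    eukaryotic genomes. Extracts introns with phase and relative position from
    genome annotations, scores them against 5' splice-site and branch-point
    motif models with percentile calibration, curates per-species presence or
    absence calls using snRNA and BUSCO evidence, builds reciprocal-best-hit
    ortholog cliques, maps intron positions into protein alignments to call
    conservation and type-conversion states, estimates ancestral intron counts
    and minor intron densities from three-species presence counts, decomposes
    minor intron loss into deletion versus conversion, and provides the
    positional-bias, phase and cell-type z-score statistics used in such
    surveys. Includes synthetic-data generators so the full pipeline runs at
    desk scale.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
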