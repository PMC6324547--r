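Package: GapTiler
Title: Gap Closing in Draft Genome Assemblies with Long-Read Tag Tiling Paths
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closes gaps (runs of 'N') in draft genome scaffolds using long
    sequencing reads. Each read is fragmented into a tiling path of
    fixed-length tags; tag alignments to the scaffolds are scored by an
    alignment-coverage formula and refined by three filtration rounds
    (orientation majority vote, order consistency against a median reference
    tag, and rescue of multi-mapped tags via neighbouring unique anchors).
    Gaps are then classified into three types according to whether one read,
    two reads, or a single flank provides anchored support, and are filled by
    read sequence with explicit N-padding arithmetic, iterating to
    convergence. Includes a synthetic-data module (genomes with planted
    repeats, random and repeat-derived gaps, error-bearing long-read
    simulation) and truth-based evaluation with contig N50 statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: Assembly, Alignment, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
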