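Package: chromoscaf
Title: Chromosome-Scale Assembly Curation, Scaffolding and Rearrangement Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning long-read contig assemblies into chromosome-scale
    scaffolds and auditing them against reference genomes. Implements
    dual-assembly reconciliation and zero-coverage contig curation,
    reference-guided ordering and orientation of contigs with gap estimation,
    gap-targeted local reassembly and contig-end stitching, classification and
    counting of large-scale rearrangements (fusions/fissions, intra-chromosomal
    translocations, inversions) from whole-genome alignments, standard assembly
    metrics (N50, ungapped length, top-n completeness), and a synthetic-truth
    generator so every stage is testable without external data. Operates on
    standard formats (FASTA, PAF, AGP, BED); alignments are pluggable and can
    come from any long-read or whole-genome aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
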