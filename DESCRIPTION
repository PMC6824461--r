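Package: hicscaffold
Title: Chromosome-Length Genome Scaffolding from Hi-C Contact Maps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Orders and orients pre-assembled contigs and scaffolds into
    chromosome-length assemblies using Hi-C contact information. Provides
    coverage-based bin filtering with robust (MAD) outlier removal, iterative
    matrix balancing, misassembly detection through insulation
    (TAD-separation) scores, iterative maximum-spanning-tree scaffold joining
    with hub resolution and contact-decay based orientation scoring,
    reinsertion of small scaffolds, and FASTA, AGP and UCSC liftover chain
    output. A synthetic Hi-C simulator with ground truth and an assembly
    evaluator make the whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
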