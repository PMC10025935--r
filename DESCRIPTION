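Package: metanopore
Title: Characterization and Simulation of Nanopore Metagenomic Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes Oxford Nanopore metagenomic sequencing data and
    simulates multi-sample metagenomes true to those characteristics.
    Detects chimeric (split) reads via best compatible alignment sets with
    circular-origin bridge merging, estimates microbial abundances at base
    level with an expectation-maximization treatment of multialigned
    segments, models read/segment/gap lengths by kernel density estimation,
    learns a shrinkage-rate Markov model for the source species of
    consecutive chimeric segments, and fits an empirical basecall-error
    model. The simulator generates reads for communities of linear and
    circular genomes with chimeric artifacts, abundance deviation, and
    basecall errors, with per-segment ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
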