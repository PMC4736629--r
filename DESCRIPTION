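Package: repeatome
Title: Low-Pass Shotgun Characterization of Plant Repeatomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: De novo characterization of the repetitive fraction of a plant
    genome from unassembled low-pass shotgun reads. Provides a synthetic
    genome simulator with planted repeat families and ground-truth
    annotations; frequent l-mer seeded greedy consensus extension for de novo
    repeat discovery with length, copy-number and complexity filters;
    overlap-based candidate assembly and identity clustering; similarity
    classification against labelled exemplar libraries; masking-based genome
    abundance and copy-number estimation with reciprocal library-completeness
    metrics; tandem satellite monomer inference, conservation profiling and
    in silico restriction-digest ladders; and paralog-based phylogenetics
    with neighbor-joining trees, bootstrap supports, Kimura two-parameter
    distances and molecular-clock dating of subclade splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
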