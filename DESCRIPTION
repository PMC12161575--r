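Package: regumine
Title: Regulation-Based Genome Mining of Bacterial Regulons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the direct regulon of a bacterial transcription factor by
    combining motif scanning with co-expression analysis. Builds a position
    weight matrix from curated binding sites, scans an annotated genome with an
    exact p-value-calibrated score floor, refines the threshold from the
    non-coding/coding hit ratio, corrects an RNA-seq correlation matrix for
    mean-expression bias (first-principal-component removal and spatial
    quantile normalization), assembles the regulon through anti-correlation
    filtering and operon expansion, and detects biosynthetic loci from
    declarative protein-domain rules. Includes a synthetic-data generator with
    planted regulons so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
Suggests:
    sva,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'calibration.R'
    'cluster-rules.R'
    'coexpression.R'
    'genome.R'
    'regumine-package.R'
    'motif.R'
    'pipeline.R'
    'regulon.R'
    'report.R'
    'scan.R'
    'synthetic.R'
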