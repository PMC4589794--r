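Package: mesic
Title: Single-CpG Methylation Estimation from MeDIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates absolute 5-methylcytosine (5mC) levels at single-CpG
    resolution from MeDIP-seq data. Each CpG site is described by a
    404-dimensional feature vector (per-base reads-per-million signal over a
    400 bp window, a distance-weighted CpG coupling factor, GC content, CpG
    density and mean conservation); genomic-element-stratified random-forest
    regression models map features to methylation levels, with predictions
    averaged over multi-element membership. Includes derivation of per-CpG
    reference 5mC from bisulfite and TAB sequencing counts (coverage and
    binomial non-conversion filtering, BS minus TAB subtraction), evaluation
    metrics (Pearson correlation, concordance, CpG-density-stratified error),
    robustness harnesses (read subsampling, label noise, no-read
    discrimination), sliding-window differentially methylated region calling,
    and a self-contained synthetic methylome and MeDIP-seq simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    randomForest,
    jsonlite
Suggests:
    e1071,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
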