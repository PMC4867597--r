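Package: riboclip
Title: CLIP-Seq Peak Calling and Ribosome Profiling Metagene Analysis for
    RNA-Helicase Target Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studies that combine CLIP-seq mapping of an
    RNA-binding protein's transcriptome-wide targets with ribosome profiling of
    translational consequences. Provides control-subtracted sliding-window
    Poisson peak calling with Benjamini-Hochberg correction, per-genomic-class
    feature densities, region-normalized metagene binning of peaks and
    ribosome footprints, Kolmogorov-Smirnov tests for ribosome occupancy
    redistribution between conditions, ribosome half-transit-time estimation
    from paired PMS/PRS labeling time courses by dual linear regression, and
    MA-style target/non-target expression comparison. A seeded synthetic-data
    generator emulates the statistical structure these analyses assume
    (AUG-proximal 5'-UTR binding, initiation/termination ramps, post-stop
    drop-off, condition-specific occupancy shifts) so the full pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, RiboSeq, PeakDetection, Coverage
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'io.R'
    'clip.R'
    'ribo.R'
    'expression.R'
    'riboclip-package.R'
    'simulate.R'
    'transit.R'
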