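Package: rerepCGH
Title: Re-Replication Profiling of Yeast Replication Origins from Array CGH
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying DNA replication origin re-initiation in
    budding yeast from two-channel array comparative genomic hybridization
    (aCGH) experiments. Probe-level Cy5/Cy3 intensity tables are normalized
    to absolute DNA content, filtered with a moving-window median, smoothed
    by circular Fourier convolution, and averaged into composite profiles
    with replicate standard deviations. Peak heights above the 2C M-phase
    baseline are converted into re-initiation efficiencies with propagated
    error, compared against negative-control strains by Welch's t-test, and
    translated into the fraction of cells that have re-initiated an origin.
    The package also provides a generative simulator of re-replication and
    S-phase aCGH samples, an origin-relative coordinate toolkit for
    constructing linker-scan, insertion and deletion mutants around ORC
    binding sites, and the supporting assay statistics (2^-ddCt ChIP-qPCR
    fold enrichment and plasmid mitotic stability).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
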