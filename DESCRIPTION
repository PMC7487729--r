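Package: tftarget
Title: Predict Transcription Factor Targets and Combined Regulatory
    Function from Binding and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks the direct gene targets of a transcription factor by
    integrating ChIP-seq binding peaks with differential expression under
    factor perturbation. Peaks are assigned to regions of interest within
    a window, scored with an exponential distance-decay kernel, and summed
    into per-region regulatory potentials; potentials and signed
    expression statistics are combined into rank products. For two
    factors assayed in comparable experiments, a regulatory-interaction
    term (the product of the two signed statistics) classifies shared
    targets as cooperatively or competitively regulated, and grouped
    empirical cumulative distribution functions compared with two-sample
    Kolmogorov-Smirnov tests decide the dominant mode. Includes a
    simulator that plants cooperative or competitive structure for
    validation, and a command-line interface.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    ggplot2,
    jsonlite,
    grDevices,
    optparse,
    rlang,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
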