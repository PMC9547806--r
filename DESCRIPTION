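Package: clusterlab
Title: Antibody-Mediated Receptor Crosslinking Simulation and Fluorescence
    Image Quantification for Acetylcholine-Receptor Autoimmunity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how combinations of bivalent antibodies with
    different subunit specificities crosslink pentameric acetylcholine
    receptors into aggregates, and for quantifying the downstream readouts
    used in myasthenia gravis research. Implements a stochastic
    random-sequential-attachment model of bivalent antibody binding to
    multi-epitope receptors (dimer, linear-chain and branched-lattice
    regimes), synthetic generators for clustering time-lapses, multichannel
    neuromuscular-junction images, flow-cytometry event tables and calcium
    traces with ground truth, Renyi-entropy automatic thresholding with
    size-filtered cluster extraction and growth-rate estimation,
    neuromuscular-junction morphometry (receptor retention, complement
    deposition, fragmentation), and assay statistics (geometric-mean
    fluorescence ratios, four-parameter logistic EC50 fits, combination
    synergy indices, and permutation tests for Spearman correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
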