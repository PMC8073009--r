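Package: terminus
Title: Pooled-Competition Fitness, Proteome Sectors, and Translation
    Termination Stress Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative bacterial physiology built around
    perturbations of translation termination. Infers relative fitness from
    UMI-collapsed barcoded pooled-competition count time series with Poisson
    counting-error models, bootstrap slope ranges and precision audits;
    quantifies per-gene expression (edge-trimmed densities, rpkm excluding
    rRNA/tRNA, proteome synthesis fractions, translation efficiency, regulon
    and proteome-sector fractions with transcriptome-to-proteome calibration);
    fits bacterial growth-law lines and predicts proteome-compression growth
    defects from gratuitous regulon expression; computes stop-codon-aligned
    metagene traces, ribosome-queue metrics and stop-codon readthrough scores
    from ribosome-profiling pileups; tests operon stoichiometry changes with a
    stop-codon label-reshuffling permutation null; and includes a stochastic
    ribosome-traffic (exclusion process) simulator plus synthetic-data
    generators so the full pipeline runs and validates offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    methods,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
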