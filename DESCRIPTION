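Package: oligocgh
Title: Array Comparative Genomic Hybridization on Oligonucleotide Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of array comparative genomic hybridization
    (aCGH) experiments that hybridize labeled genomic DNA to long-oligonucleotide
    gene-expression arrays, as used to compare closely related snail (Littorina)
    species and populations. Provides in-silico array design (fragmentation of
    source sequences into pseudo-genes and GC-targeted 60-nt probe selection), a
    forward simulator of probe-level log2 hybridization signals with copy-number,
    GC-content, sequence-mismatch, exon-boundary, dye and subarray effects,
    quantile and ANOVA-residual normalization, an EM fit of a three-component
    normal mixture for copy-number classification (deletion / single-copy /
    duplicated), per-gene ANOVA and t-tests with Benjamini-Hochberg FDR control,
    neighbour-joining trees from divergent-gene counts, bootstrapped single-linkage
    clustering, principal component analysis, and an ungapped seed-and-extend
    probe-to-genome matcher for hybridization sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    ape,
    limma,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
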