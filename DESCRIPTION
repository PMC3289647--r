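Package: erevar
Title: Estrogen Response Element Variant Discovery and Stratified Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of DNA variants in
    estrogen-receptor binding sites and their association with case-control
    phenotypes. Scans IUPAC-masked genome sequence for estrogen response
    element (ERE) half-site cores (GGTCA/TGACC) containing potentially
    site-disrupting SNPs, intersects chromatin-immunoprecipitation (ChIP)
    binding-region sets to a consensus, assembles a candidate SNP panel with
    linkage-disequilibrium proxy substitution, applies standard genotype
    quality control (missingness, minor allele frequency, Hardy-Weinberg
    exact test in controls), and runs sex- and disease-stratified allelic
    Fisher exact association with Woolf confidence intervals and study-wide
    Bonferroni correction. Includes a synthetic-data generator that emits
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
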