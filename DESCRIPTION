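Package: ldarray
Title: LD-Aware Design and Analysis of Custom Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and analysing trait-enriched custom
    genotyping arrays. Constructs LD-defined fine-mapping regions (signal
    and locus fine mapping) around GWAS index SNPs using a reference
    haplotype panel and a recombination map with hotspot detection; selects
    replication SNP panels as top independent association signals; assembles
    multi-trait submissions into a deduplicated array manifest; and provides
    the enriched-array-aware statistical machinery such arrays require:
    null-SNP-set selection for genomic control, LD-pruned SNP sets for
    structure and kinship analysis, method-of-moments IBD estimation, a
    genetic relationship matrix, and a permutation test for SNP-set overlap
    across traits. Includes fully seeded synthetic-data generators (haplotype
    panels with hotspot-punctuated recombination, pedigrees with known IBD,
    stratified case-control studies, summary statistics with planted
    signals) so every stage is testable without external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
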