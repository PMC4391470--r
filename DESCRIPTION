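Package: gwasbench
Title: Simulation Benchmark for Gene- and Pathway-Level GWAS Secondary Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates LD-structured SNP genotypes and polygenic case-control
    phenotypes under an additive liability model, runs single-SNP logistic
    regression GWAS, and benchmarks eleven gene-level aggregation tests
    (Fisher, Sidak, Simes, FDR, truncated product, GATES, weighted GATES,
    HYST, weighted HYST, VEGAS, VEGAS top-10%) and seven pathway-level set
    tests (GSA-SNP, permutation GSEA, ALIGATOR, a MAGENTA-like corrected
    enrichment, SNP Ratio Test, Plink-style set test, pathway HYST) against
    the known causal architecture, scoring sensitivity, specificity,
    false-positive proportions and pathway rank correlations. Reads and
    writes PLINK text genotypes, BED gene annotation and GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
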