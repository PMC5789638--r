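Package: rohcompare
Title: Comparing Runs of Homozygosity Between SNP Array and Low-Coverage
    Sequencing Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) with a PLINK-style
    sliding-window scanner with tunable heterozygote tolerance, and compares
    ROH called from SNP array genotypes against ROH called from low-coverage
    whole-genome sequencing genotypes for the same individuals. Provides
    per-population site quality control (minor allele frequency and exact
    Hardy-Weinberg filtering), cross-technology genotype concordance
    decomposition, the ep(P,h) statistic of observed heterozygote leakage
    inside called ROH, per-individual ROH summaries with Pearson and
    Mann-Whitney-Wilcoxon comparison machinery, and a seeded dual-channel
    genotype simulator with planted autozygous tracts for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
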