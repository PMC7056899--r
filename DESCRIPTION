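Package: panelGBLUP
Title: Low-Density SNP Panel Evaluation for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate how far SNP genotyping density can be reduced
    before genomic prediction breaks down in family-structured breeding
    programs, as commonly run in aquaculture sib-testing schemes. Provides a
    gene-dropping simulator of full-sib populations with polygenic traits of
    known heritability, PLINK text and binary genotype input/output,
    PLINK-style quality control with an exact Hardy-Weinberg test,
    replicated low-density SNP panel sampling on a density grid, the
    frequency-weighted genomic relationship matrix, restricted maximum
    likelihood (REML) variance-component estimation in the eigenbasis of the
    relationship matrix, genomic best linear unbiased prediction (GBLUP),
    and replicated k-fold cross-validation aggregated into prediction
    accuracy curves and proportion-of-full-panel-accuracy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
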