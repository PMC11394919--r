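Package: rsnpscan
Title: Discovery of Regulatory SNPs from Paired Allele-Specific Binding and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale pipeline for discovering regulatory SNPs
    (rSNPs) from paired allele-specific ChIP-seq (H3K4me3, H3K27ac) and
    RNA-seq evidence in heterozygous individuals. Calls heterozygous sites
    from pooled per-individual allele depths, tests each site for allelic
    asymmetry with an exact binomial test under Benjamini-Hochberg control,
    aggregates SNP-level allelic expression to gene level with a
    pseudo-phasing Monte Carlo ("MBASED-lite") test, intersects promoter
    allele-specific-binding SNPs with allele-specifically expressed genes
    to assemble the rSNP panel, and characterizes the panel downstream:
    catalog window matching with 2x2 enrichment (odds ratio, Woolf CI,
    Fisher and chi-square p-values), per-trait ranking, negative-binomial
    Wald differential expression with DEG-promoter intersection, PPI hub
    selection by merged top-20 centralities (degree, betweenness, stress),
    MCODE module detection, hypergeometric over-representation analysis,
    and ROC/AUC biomarker screening. A synthetic-data module generates
    every input with known ground truth so all stages are testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr,
    withr
Suggests:
    DESeq2,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
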