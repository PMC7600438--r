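Package: cffpipe
Title: Germline Risk-Allele and Rare-Variant Carrier Analysis for Cancer-Free Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for germline whole-genome analyses of
    cancer-free family cohorts against public reference populations:
    GWAS risk-SNP selection with greedy LD pruning, cohort-versus-reference
    risk-allele odds ratios with Bonferroni control, polygenic risk-allele
    quartile and trend analysis, a conjunctive variant-prioritization
    cascade (MAF, CADD, conservation and deleteriousness consensus),
    carrier-probability aggregation with bias-corrected accelerated (BCa)
    bootstrap confidence intervals for carrier odds ratios, and a
    high-risk-gene ClinVar screen. Ships a synthetic-data generator that
    emulates every input (Hardy-Weinberg genotypes, ExAC-style site
    counts, annotation tables, risk-SNP panels with planted LD blocks) so
    the whole pipeline is testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
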