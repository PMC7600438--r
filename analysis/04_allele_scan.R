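# Per-SNP risk-allele frequency comparison of the cohort against the
# large reference, with Wald odds ratios and the Bonferroni-adjusted
# significance level.  The simulated cohort is drawn from the reference
# frequencies, so this is a null scan: about 5% of rows should be
# nominally significant and essentially none Bonferroni-significant.

source(file.path("analysis", "00_setup.R"))

run_stage("allele_scan", WORKSPACE, CFG)

scan <- read_report(file.path(WORKSPACE, "allele_scan.tsv"))
say("scanned %d SNPs; nominal (p < 0.05): %d (%.1f%%);"
    , nrow(scan), sum(scan$nominal, na.rm = TRUE),
    100 * mean(scan$nominal, na.rm = TRUE))
say("Bonferroni-significant rows: %d",
    sum(scan$bonferroni_significant, na.rm = TRUE))
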