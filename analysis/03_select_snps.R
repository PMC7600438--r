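# Apply the six GWAS risk-SNP exclusion criteria (unspecified risk
# allele, near-0.5 or unspecified MAF, OR below 1.04, subtype-specific
# association, absence from the reference panel, LD pruning at r2 > 0.8)
# and report every removal with its first matching criterion.

source(file.path("analysis", "00_setup.R"))

run_stage("select_snps", WORKSPACE, CFG)

excl <- read_report(file.path(WORKSPACE, "snp_exclusions.tsv"))
kept <- read_risk_snps(file.path(WORKSPACE, "risk_snps_retained.tsv"))
say("retained %d SNPs; excluded %d", nrow(kept), nrow(excl))
print(table(criterion = excl$criterion))
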