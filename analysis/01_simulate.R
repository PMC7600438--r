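# Generate every input the downstream stages consume: a 51-individual
# cohort (genotypes, depths, QUALs), GWAS risk-SNP panels with planted
# exclusions and LD blocks, a 294-individual reference panel, gnomAD-style
# allele frequencies, annotated rare variants with known filter-stage
# profiles, and ExAC-scale ClinVar-labelled site counts.

source(file.path("analysis", "00_setup.R"))

run_stage("simulate", WORKSPACE, CFG)

inv <- read_report(file.path(WORKSPACE, "simulate_report.tsv"))
say("simulated %d artifact tables into %s", nrow(inv), WORKSPACE)
say("cohort: %d individuals; risk SNPs: %d; rare variants: %d",
    CFG$simulate$n_cohort, sum(CFG$simulate$n_snps),
    CFG$simulate$n_rare_variants)
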