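# High-risk panel screen: rare missense/LoF variants in BRCA1/2, APC,
# MLH1, MSH2, MSH6, MUTYH, PMS2 and HOXB13, with CADD, conservation and
# deleteriousness votes and ClinVar significance; plus the per-gene
# probability that a reference individual carries a ClinVar-pathogenic
# variant.

source(file.path("analysis", "00_setup.R"))

run_stage("highrisk", WORKSPACE, CFG)

screen <- read_report(file.path(WORKSPACE, "highrisk.tsv"))
refp <- read_report(file.path(WORKSPACE, "highrisk_reference.tsv"))
hits <- screen[screen$snp_id != "Not found", ]
say("panel hits: %d variants across %d genes; %d genes with none",
    nrow(hits), length(unique(hits$gene)),
    sum(screen$snp_id == "Not found"))
for (i in seq_len(nrow(refp))) {
  say("%s: %d sites, %d pathogenic, P(carrier) = %.3f%%",
      refp$gene[i], refp$n_variants[i], refp$n_pathogenic[i],
      100 * refp$p_pathogenic_carrier[i])
}
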