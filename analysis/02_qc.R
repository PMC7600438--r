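# Cohort quality control: mask calls under 5 reads, drop variants with
# QUAL not above 20, apply the 10-reads-in-90%-of-samples site mask, and
# look for cryptic duplicates/relatives by pairwise dosage concordance.

source(file.path("analysis", "00_setup.R"))

run_stage("qc", WORKSPACE, CFG)

qc <- read_report(file.path(WORKSPACE, "qc_report.tsv"))
rel <- read_report(file.path(WORKSPACE, "relatedness.tsv"))
say("QC: %s of %s variants survive QUAL + site mask",
    qc$value[qc$metric == "variants_after_mask"],
    qc$value[qc$metric == "variants_in"])
say("flagged related pairs (concordance > %.2f): %d",
    CFG$qc$relatedness_flag, nrow(rel))
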