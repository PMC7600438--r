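# Variant prioritization: the conjunctive cascade (rarity in every
# frequency source, CADD > 10, 2-of-3 conservation vote, strict-majority
# deleteriousness vote) over both predisposition gene lists and both
# consequence classes, with a per-variant per-stage audit.

source(file.path("analysis", "00_setup.R"))

run_stage("prioritize", WORKSPACE, CFG)

audit <- read_report(file.path(WORKSPACE, "prioritization_audit.tsv"))
surv <- read_report(file.path(WORKSPACE, "prioritization_survivors.tsv"))
for (ln in unique(audit$gene_list)) {
  for (cl in unique(audit$class)) {
    a <- audit[audit$gene_list == ln & audit$class == cl, ]
    s <- surv[surv$gene_list == ln & surv$class == cl, ]
    say("%s / %s: %d variants in scope, %d pass (%d genes)",
        ln, cl, nrow(a), sum(a$final == "pass"),
        length(unique(s$gene)))
  }
}
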