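# Polygenic burden: per-individual risk-allele totals, quartiles defined
# on the reference panel, per-quartile odds ratios against the lowest
# quartile, and the logistic trend test over quartile index.

source(file.path("analysis", "00_setup.R"))

run_stage("burden", WORKSPACE, CFG)

burden <- read_report(file.path(WORKSPACE, "burden.tsv"))
for (ct in unique(burden$cancer_type)) {
  tab <- burden[burden$cancer_type == ct, ]
  say("%s: quartile ORs %s; trend p = %.3f", ct,
      paste(sprintf("%.2f", tab$or), collapse = " / "),
      tab$trend_p[1])
}
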