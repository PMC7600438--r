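# cffpipe

Germline risk-allele and rare-variant carrier analysis for cancer-free
cohorts.

## What this is for

Cohorts selected for the *absence* of disease — for example, elderly
individuals from families with no cancer history — invert the usual
case-control question: do they carry **fewer** cancer risk alleles than
the population at large?  Testing that requires comparing a small
whole-genome-sequenced cohort against public references that expose only
aggregates: gnomAD/ExAC-style per-site allele counts (AC, Hom, AN),
a small reference panel with individual genotypes (1000 Genomes-style),
and GWAS catalogues of common risk SNPs.  `cffpipe` is for statistical
geneticists and genetic epidemiologists who need that comparison as a
tested, reproducible pipeline rather than a one-off script stack.

The pipeline covers:

* **Cohort QC** — per-call depth masking (≥ 5 reads), per-variant QUAL
  filtering (> 20), a 10-reads-in-90%-of-samples site mask, and a
  pairwise dosage-concordance relatedness check.
* **Risk-SNP selection** — six exclusion criteria for published GWAS
  hits, including greedy LD pruning at genotypic r² > 0.8 with a
  deterministic max-effect representative.
* **Allele association** — per-SNP cohort-vs-reference odds ratios from
  the 2×2 closed form OR = ad/bc with Wald inference (identical to a
  binary-covariate logistic fit), under Bonferroni control.
* **Polygenic burden** — per-individual risk-allele totals,
  reference-defined integer quartiles, per-quartile ORs and a logistic
  trend test over quartile index 1–4.
* **Variant prioritization** — a conjunctive cascade: MAF < 0.001 in
  every available source, scaled CADD > 10, a ≥ 2-of-3 conservation vote
  (GERP > 2.0, PhastCons > 0.3, PhyloP ≥ 3.0), and a strict majority of
  ten missense deleteriousness predictors, with a per-variant per-stage
  audit.
* **Carrier statistics** — per-site carrier frequency
  q = (AC − Hom)/(AN/2), the independent-sites aggregate
  P = 1 − Π(1 − qᵢ), the carrier odds ratio
  OR = P_c(1 − P_r) / ((1 − P_c)P_r), and a bias-corrected and
  accelerated (BCa) bootstrap CI over cohort individuals (B = 10,000).
* **High-risk gene screen** — rare missense/LoF variants in BRCA1/2,
  APC, MLH1, MSH2, MSH6, MUTYH, PMS2, HOXB13 with ClinVar significance,
  plus per-gene reference pathogenic-carrier probabilities.
* **Synthetic data** — generators for every input (HWE genotypes,
  consistent site-count triples, threshold-engineered annotations,
  risk-SNP panels with planted LD blocks, burden scenarios with known
  effects), so the whole pipeline runs and is tested without protected
  data.

See `vignettes/carrier-burden-methods.Rmd` for the full model
description, parameter rationale and limitations.

## Worked example

Re-deriving a published-style quartile table from printed per-quartile
counts (294 reference individuals vs 51 cohort individuals, prostate
cancer):

```r
library(cffpipe)

tab <- quartile_table_from_counts(
  n_reference = c(91, 64, 86, 53),
  n_cohort    = c(10, 10, 10, 21),
  labels      = c("<=89", "90-93", "94-97", ">97"))
#>   label n_reference n_cohort     or ci_low ci_high      p
#> 1  <=89          91       10 1.0000     NA      NA     NA
#> 2 90-93          64       10 1.4219 0.5593  3.6147 0.4597
#> 3 94-97          86       10 1.0581 0.4197  2.6678 0.9047
#> 4   >97          53       21 3.6057 1.5790  8.2334 0.0023
attr(tab, "trend_p")
#> trend p = 0.0055
```

Individuals in the top risk-allele quartile are 3.61 times as likely to
be cohort members as those in the bottom quartile, and membership odds
rise significantly across quartiles (trend p = 0.0055).

Carrier statistics from reference site counts:

```r
q <- carrier_freq(ac = c(40, 12, 7), hom = c(1, 0, 0), an = rep(66740, 3))
#> per-site carrier frequencies: 0.00117 0.00036 0.00021
carrier_probability(q)
#> aggregate P = 0.00174

ind <- c(rep(1, 3), rep(0, 48))   # 3 carriers among 51 individuals
ci <- bca_ci(ind, p_reference = 0.15, n_boot = 10000, seed = 7)
#> carrier OR 0.354, 95% BCa CI [0.00, 0.76]
```

With 3 of 51 cohort members carrying a qualifying variant against a 15%
reference carrier probability, the cohort's carrier odds are about a
third of the reference's, and the bootstrap lower bound reaches 0
because resamples with no carriers map to OR 0.

The full chain, end to end on synthetic data:

```r
cfg <- default_config(seed = 1)
run_pipeline("workspace", cfg)   # simulate -> qc -> ... -> highrisk
```

or step by step via the numbered drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_qc.R
# ... through
Rscript analysis/09_published_counts.R
```

Each stage writes TSV reports (headers echo the configuration hash and
seed) under `results/workspace/`; reruns with the same configuration are
byte-identical.

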