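---
title: "Methods: germline risk-allele burden and rare-variant carrier analysis"
author: "cffpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline risk-allele burden and rare-variant carrier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cffpipe)
```

## The problem

Cohorts selected for an *absence* of disease — here, elderly individuals
from families with no cancer history across generations — pose the mirror
image of the usual case-control question: do these individuals carry
*fewer* cancer risk alleles than the population at large?  Answering it
requires comparing a small sequenced cohort (tens of individuals) against
public reference populations that publish only aggregate data: per-site
allele counts from exome/genome aggregation databases, individual
genotypes from a small reference panel, and GWAS catalogues of common
risk SNPs.  `cffpipe` implements that comparison end to end, on both the
common-variant (polygenic) and rare-variant (carrier probability) sides,
and ships a synthetic-data generator so every stage is testable without
access to protected genotypes.

## Cohort quality control

Genotype calls with fewer than 5 supporting reads are set to missing, and
variants whose QUAL is not strictly above 20 are removed; both readings
are deliberate ("a minimum of 5" is inclusive, "higher than 20" is
exclusive) and are applied literally.  Site-level analyses additionally
require at least 10 reads in at least 90% of individuals
(`site_mask()`).  Relatedness is screened by pairwise dosage concordance
— the fraction of co-called sites with identical dosage — with pairs
above 0.9 flagged for review, not removed automatically.  No published
statistic or threshold exists for this step in the protocol we
re-implement, so plain concordance was chosen for transparency; for
unrelated individuals at a site with allele frequency $f$ the expected
concordance is $\sum_g P(g)^2$ (0.375 at $f = 0.5$), so duplicates and
first-degree relatives separate cleanly when concordance is computed on
*common* variants.  On rare-variant matrices almost every pair is
concordant at almost every site, which is why the pipeline's QC stage
estimates concordance from the common risk-SNP dosages.

## Risk-SNP selection

Published GWAS hits enter the analysis only if they survive six
exclusions: (1) unspecified risk allele; (2) unspecified MAF or MAF
strictly inside (0.45, 0.55) — the open interval is a documented choice,
so a MAF of exactly 0.45 is retained, and both bounds are configurable;
(3) published risk-allele OR below 1.04; (4) associations restricted to a
tumour subtype (ER status or histology); (5) absence from the reference
genotype panel; (6) LD pruning.  Each removed SNP is reported with the
*first* criterion that caught it, so exclusion reasons partition the
removed set.

LD is measured as the squared Pearson correlation of dosages (genotypic
$r^2$) in the reference panel, not in the cohort: a 51-sample cohort
estimates $r^2$ poorly, and the lists being pruned are population-level
catalogues.  Linked clusters are connected components of the graph
joining pairs with $r^2 > 0.8$ (strictly), and exactly one SNP survives
per cluster: the one with the largest $|\ln \mathrm{OR}|$, ties broken by
smallest rsID.  The published protocol says only that one SNP of a linked
group was kept; the max-effect representative maximizes the information
retained and the deterministic tie rule makes pruning invariant to input
order, which the tests verify against an exhaustive subset search.

## Allele-frequency association and the polygenic burden

Per-SNP cohort-versus-reference comparisons use the closed-form odds
ratio of the 2×2 allele table, $\mathrm{OR} = ad/bc$, with Wald standard
error $\sqrt{1/a + 1/b + 1/c + 1/d}$, 95% CI
$\exp(\ln \mathrm{OR} \pm 1.959964\,\mathrm{SE})$ and a two-sided normal
p-value.  A logistic regression of group membership on a single binary
allele covariate yields exactly this estimate, which the tests confirm
against an iteratively reweighted fit to near machine precision; each
chromosome contributes one observation (allele-level coding), consistent
with comparing allele frequencies.  Reference allele counts are
reconstructed as $\mathrm{round}(\mathrm{AF} \cdot \mathrm{AN})$ because
aggregation databases publish frequencies and allele numbers, not counts
keyed to GWAS risk alleles.  No continuity correction is applied; a zero
cell yields a flagged undefined result.  Multiplicity is controlled by
the Bonferroni level $\alpha/m$, reported at full precision and as the
4-decimal display used in the published tables (0.05/106 → 0.0005).

The polygenic burden is the unweighted sum of risk-allele dosages per
individual.  Missing dosages contribute their Hardy–Weinberg expectation
$2 \cdot \mathrm{MAF}$ by default (configurable to contribute nothing);
the protocol is silent on this point and expectation imputation keeps
totals comparable across individuals with different missingness.
Quartile cutpoints are the 25th/50th/75th order-statistic (type-1)
percentiles of the *reference* totals, floored to integers; bins are
$\le c_1$, $c_1{+}1..c_2$, $c_2{+}1..c_3$, $> c_3$, so ties fall in the
lower bin and the printed bin style (≤87, 88–91, …) is reproduced
exactly.  Per-quartile ORs against the lowest quartile come from the same
2×2 closed form — on the published count tables this reproduces the
printed ORs to their 2-decimal display — and the trend test is a
maximum-likelihood logistic regression of cohort membership on quartile
index coded 1–4 as a continuous covariate, with a two-sided Wald p on the
slope.  Which SAS statistic (Wald, score, LR) produced the published
trend p is unstated; the Wald choice lands on 0.0055 for the
prostate-cancer counts, matching the printed value, and the tests allow
±0.002 for this method dependence.

## The prioritization cascade

A variant is *potentially pathogenic* when it survives a conjunction of
stages:

* **Rarity** — allele frequency strictly below 0.001 in *every* available
  source (1000 Genomes-style, non-Finnish European non-TCGA exome
  reference, local dataset).  An absent source passes (frequency unknown
  is read as rare); a variant with no source at all is "not evaluated".
* **CADD** — scaled (PHRED-like) score strictly above 10, i.e. roughly
  the top decile of possible substitutions.
* **Conservation** — at least 2 votes among GERP > 2.0, PhastCons > 0.3
  and PhyloP ≥ 3.0.  PhyloP's threshold is the one inclusive comparison,
  matching its published statement.
* **Deleteriousness** — strictly more than half of the available calls
  among ten missense predictors (SIFT, PolyPhen-2 HDIV/HVAR, LRT,
  MutationTaster, MutationAssessor, FATHMM, MetaSVM, MetaLR, PROVEAN)
  say deleterious; with all ten available this is the ≥ 6/10 rule.

Because the cascade is a pure conjunction, the surviving set equals the
intersection of per-stage pass sets and cannot depend on stage order;
the tests check this by permutation and by recomputing each stage
independently.  Tightening any threshold can only shrink the survivors.

Two policies deserve explicit statement.  First, loss-of-function
variants (stop gain/loss, splice site, frameshift indel) skip the
conservation and deleteriousness votes and are filtered on rarity and
CADD alone: missense predictors do not score such variants, and the
published LoF counts could not have passed a ten-missense-tool vote.
Whether conservation was required of LoF variants is unstated; the
exemption is this package's documented choice.  Second, the intolerance
screen (three gene-intolerance ranks plus the missense Z-score) annotates
the audit but blocks nothing by default, because the protocol reports
that intolerance was considered without stating thresholds; supplying
thresholds in the configuration turns it into a hard filter.  Missing
CADD or conservation scores default to lenient pass-through
("not evaluated"), with a strict mode that fails missing CADD.

ClinVar strings are normalized by collapsing compound values (e.g.
"Likely benign/US") to the *most severe* listed category, with the raw
string retained for reports; the published tables print compound values
without stating a collapse rule, so severity-max is a documented choice
biased toward sensitivity in a screening context.

## Carrier probabilities and the bootstrap

For a reference site published as (AC, Hom, AN), the fraction of
individuals carrying at least one alternate allele is

$$q_i = \frac{\mathrm{AC}_i - \mathrm{Hom}_i}{\mathrm{AN}_i/2},$$

and the probability that an individual carries at least one of $k$
qualifying variants, assuming independent sites, is

$$P = 1 - \prod_{i=1}^{k} (1 - q_i).$$

The cohort-side probability is the observed carrier fraction — the
protocol never states how it was computed, and the observed fraction is
the direct estimate when individual genotypes are available (applying the
product formula to cohort allele counts is available as an alternative).
The two probabilities are compared as
$\mathrm{OR} = P_c(1-P_r) / \big((1-P_c)P_r\big)$.

The 95% CI comes from a bias-corrected and accelerated (BCa) bootstrap
with 10,000 resamples of *cohort individuals* (their carrier indicators),
holding $P_r$ fixed: the reference is three orders of magnitude larger,
so its sampling error is negligible, and only cohort resampling can
produce the zero lower bounds seen when few cohort members carry.
Per replicate the carrier fraction and OR are recomputed; the bias
correction is $z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)$ and the
acceleration comes from the jackknife third-moment formula
$a = \sum d_i^3 / \big(6 (\sum d_i^2)^{3/2}\big)$ with
$d_i = \bar\theta_{(\cdot)} - \theta_{(-i)}$.  The jackknife uses the
carrier *fraction* as its statistic: it is a monotone reparametrization
of the OR that stays finite when a leave-one-out sample has no carriers,
where log-OR jackknife points would be infinite.  Replicates with
carrier fraction 0 or 1 map to OR 0 or ∞ and are retained at the
quantile extremes rather than discarded.  Interval endpoints are
inverse-empirical-CDF (type-1) quantiles of the replicate ORs at the BCa
adjusted levels, so a fixed seed reproduces intervals bit-exactly.  When
$z_0 = a = 0$ the mapping hands back exactly the 2.5/97.5 percentile
interval, and the tests compare endpoints against the independent
`boot` package implementation and check 95% nominal coverage of the null
OR = 1 (observed ≈ 93–96% over 500 simulated 51-individual cohorts,
within the expected band for a discrete statistic at this sample size).

## The high-risk gene screen

The fixed panel is BRCA1, BRCA2 (breast), APC, MLH1, MSH2, MSH6, MUTYH,
PMS2 (colorectal) and HOXB13 (prostate).  Missense and LoF variants in
panel genes with frequency strictly below 0.001 in a designated source
are reported with reference prevalence, CADD, conservation votes,
deleteriousness votes in "k/n available" form and ClinVar significance;
genes without a qualifying variant are reported as "Not found" and
variants without an rsID as "No dbSNP".  The frequency source is a
parameter rather than a fixed choice because the published variant list
includes entries whose exome-reference prevalence exceeds the stated
cutoff — the cutoff evidently addressed a different population than the
printed prevalence column, and the package exposes the choice instead of
resolving the contradiction silently.  Caveats (MUTYH is recessive; the
high-risk status of PMS2 and HOXB13 is debated) are carried as static
report annotations, never as logic.  The reference-side probability of
carrying a ClinVar-pathogenic/likely-pathogenic variant per gene reuses
the carrier-probability formula over the pathogenic subset.

## What the generator emulates, and what it does not

The generator produces every input: HWE cohort genotypes at given
frequencies (`gen_cohort`, with optional depth/QUAL contamination for
QC tests), reference site-count tables obtained by tabulating latent HWE
genotypes so the (AC, Hom, AN) invariants hold by construction
(`gen_reference_sites`), annotation tables whose variants are engineered
just inside or outside each cascade threshold with the ground-truth
profile retained (`gen_annotated_variants`), risk-SNP panels with
planted exclusions and LD blocks made by copying a template dosage
vector with flip noise — replacement probability $\varepsilon$ gives
$r^2 \approx (1-\varepsilon)^2$, so $\varepsilon = 0.02$ plants blocks
safely above the 0.8 threshold (`gen_risk_snp_panel`) — and paired
burden scenarios with a known per-quartile membership profile
(`gen_burden_scenario`).  The burden generator bins its pool with the
same floored-percentile rule the analysis applies, so a planted
odds-doubling profile is recovered as a trend slope of $\ln 2$ without
attenuation from boundary ties.

Defaults mirror the study design: 51 cohort individuals, a
294-individual reference panel, GWAS panels of 106/81/105 SNPs, and site
counts on a 33,370-individual exome-reference scale.  Sites are
independent except for planted LD blocks — deliberately, since the
carrier-probability formula itself assumes independence.  The generator
does **not** attempt realistic site-frequency spectra, background LD,
population structure, sequencing error profiles or annotation
correlations (e.g. between CADD and conservation).  Passing tests
therefore demonstrate that the machinery is correct under the model's own
assumptions, not that those assumptions hold in real data.

## Numerical choices and degenerate inputs

All boundary comparisons follow the published wording literally: depth
≥ 5, QUAL > 20, callable fraction ≥ 0.9, MAF < 0.001, CADD > 10,
GERP > 2.0, PhastCons > 0.3, PhyloP ≥ 3.0, strict predictor majority,
$r^2 > 0.8$, OR ≥ 1.04 retained, MAF in the open interval (0.45, 0.55)
removed.  Zero cells in 2×2 tables yield flagged undefined ORs rather
than continuity corrections.  A degenerate reference probability (0 or
1) leaves the carrier OR undefined; identical carrier indicators
collapse the bootstrap interval to the point estimate, flagged.  An
all-equal totals vector has no quartiles and errors.  Validation is
total: every input row is either accepted or appears in a rejection
report with its reason, and accepted plus rejected counts equal the
input count.

Problem sizes in the shipped tests and analysis scripts (coverage
simulations of 500 cohorts at B = 2000, 100-variant cascade fixtures,
25 brute-force pruning instances of up to 8 SNPs, a 4,000-individual
trend-recovery scenario) are the package's own choices; they make the
full suite and the analysis chain run in well under a minute each while
leaving Monte-Carlo error comfortably inside the asserted tolerances.

## Limitations

The pipeline consumes annotations (CADD, conservation, predictor calls,
ClinVar) and never computes them; no liftover, no remote queries.  The
published per-SNP tables and carrier probabilities that depend on actual
gnomAD/ExAC/1000 Genomes payloads are not reproducible offline, and the
actual membership of the two predisposition gene lists (the 723- and
114-gene roles) is external content; the shipped fixtures carry the
structure, not the identities.  What *is* reproduced from print are the
quartile odds ratios, trend tests and Bonferroni levels, which the
acceptance script recomputes from the published count tables at run
time.
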