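# Cohort-versus-reference risk-allele association: closed-form 2x2 odds
# ratios with Wald inference (identical to a binary-covariate logistic
# fit), Bonferroni significance levels, and the per-SNP scan report.

#' Odds ratio with Wald inference from a 2x2 allele table
#'
#' Cells are `a` cohort risk alleles, `b` cohort other alleles, `c`
#' reference risk alleles, `d` reference other alleles.  OR = (a d)/(b c);
#' SE(ln OR) = sqrt(1/a + 1/b + 1/c + 1/d); the 95% CI is
#' exp(ln OR +/- 1.959964 SE) and the p-value the two-sided normal tail of
#' ln OR / SE.  This closed form equals the odds ratio from a logistic
#' regression of group membership on a binary allele covariate.  No
#' continuity correction is applied: a zero cell yields an undefined
#' (`NA`) result with `zero_cell = TRUE`.
#'
#' All arguments are vectorized.
#'
#' @param a,b,c,d non-negative counts
#' @param conf_level confidence level for the Wald interval
#' @return data.frame with columns or, se_log_or, ci_low, ci_high, p,
#'   zero_cell
#' @export
two_by_two_or <- function(a, b, c, d, conf_level = 0.95) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("counts must be >= 0")
  zero <- (a == 0 | b == 0 | c == 0 | d == 0)
  or <- ifelse(zero, NA_real_, (a * d) / (b * c))
  se <- ifelse(zero, NA_real_, sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci_low <- exp(log(or) - z * se)
  ci_high <- exp(log(or) + z * se)
  p <- 2 * pnorm(-abs(log(or) / se))
  data.frame(or = or, se_log_or = se, ci_low = ci_low, ci_high = ci_high,
             p = p, zero_cell = zero)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise error rate
#' @param m number of tests (>= 1)
#' @return list with `level` (full precision `alpha/m`) and `display`
#'   (rounded to 4 decimals, as printed in reports)
#' @export
bonferroni_level <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  level <- alpha / m
  list(level = level, display = sprintf("%.4f", round(level, 4)))
}

#' Per-SNP risk-allele frequency scan against a large reference
#'
#' For each risk SNP, compares the cohort risk-allele count against
#' reference counts reconstructed from the published allele frequency and
#' allele number as `round(AF * AN)` vs `AN - round(AF * AN)`.  Cohort
#' dosages must already be oriented to the risk allele.  SNPs missing from
#' the cohort matrix are emitted with undefined fields, never silently
#' dropped.
#'
#' @param genotypes cohort [genotype_matrix()] with columns named by rsid,
#'   dosages counting risk alleles
#' @param reference data.frame with columns rsid, af (risk-allele
#'   frequency) and an (allele number)
#' @param risk_snps risk-SNP data.frame
#' @param alpha family-wise error rate for the Bonferroni column
#' @return data.frame with one row per SNP: rsid, gene (if supplied),
#'   risk_allele, freq_reference, freq_cohort, or, ci_low, ci_high, p,
#'   nominal, bonferroni_significant
#' @export
allele_scan <- function(genotypes, reference, risk_snps, alpha = 0.05) {
  m <- nrow(risk_snps)
  bonf <- bonferroni_level(alpha, m)
  ref_idx <- match(risk_snps$rsid, reference$rsid)
  af <- reference$af[ref_idx]
  an <- reference$an[ref_idx]
  in_cohort <- risk_snps$rsid %in% colnames(genotypes)
  a <- b <- rep(NA_real_, m)
  for (i in which(in_cohort)) {
    dos <- genotypes[, risk_snps$rsid[i]]
    called <- !is.na(dos)
    a[i] <- sum(dos[called])
    b[i] <- 2 * sum(called) - a[i]
  }
  cc <- round(af * an)
  d <- an - cc
  res <- two_by_two_or(a, b, cc, d)
  out <- data.frame(
    rsid = risk_snps$rsid,
    gene = if ("gene" %in% names(risk_snps)) risk_snps$gene else NA_character_,
    risk_allele = risk_snps$risk_allele,
    freq_reference = af,
    freq_cohort = a / (a + b),
    or = res$or, ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
    nominal = !is.na(res$p) & res$p < alpha,
    bonferroni_significant = !is.na(res$p) & res$p < bonf$level)
  attr(out, "bonferroni") <- bonf
  out
}
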