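# Polygenic burden of GWAS risk alleles: per-individual totals,
# reference-defined quartiles, per-quartile odds ratios against the lowest
# quartile, and the logistic trend test over quartile index.

#' Total risk alleles per individual
#'
#' Sums risk-allele dosages over the SNP panel.  Missing dosages
#' contribute the Hardy-Weinberg expectation `2 * MAF` of the panel SNP by
#' default (`missing = "impute"`); with `missing = "drop"` they contribute
#' nothing.  An individual with no called dosage at all is `NA`.
#'
#' @param genotypes [genotype_matrix()] with columns named by rsid,
#'   dosages oriented to the risk allele
#' @param risk_snps risk-SNP data.frame supplying per-SNP `maf` for
#'   imputation; defaults to the matrix's column set with no imputation
#'   frequencies
#' @param missing `"impute"` or `"drop"`
#' @return named numeric vector of totals, one per individual
#' @export
count_risk_alleles <- function(genotypes, risk_snps = NULL,
                               missing = c("impute", "drop")) {
  missing <- match.arg(missing)
  panel <- if (is.null(risk_snps)) colnames(genotypes) else
    intersect(risk_snps$rsid, colnames(genotypes))
  g <- unclass(genotypes)[, panel, drop = FALSE]
  filled <- g
  if (missing == "impute" && !is.null(risk_snps)) {
    maf <- risk_snps$maf[match(panel, risk_snps$rsid)]
    expect <- matrix(2 * maf, nrow(g), ncol(g), byrow = TRUE)
    filled[is.na(g)] <- expect[is.na(g)]
  } else {
    filled[is.na(g)] <- 0
  }
  totals <- rowSums(filled)
  totals[rowSums(!is.na(g)) == 0] <- NA_real_
  totals
}

#' Quartile cutpoints from reference totals
#'
#' Cutpoints are the empirical 25th/50th/75th percentiles of the reference
#' totals (type-1, i.e. order-statistic, quantiles) floored to integers.
#' Bins are `<= c1`, `c1+1 .. c2`, `c2+1 .. c3`, `> c3`, so ties fall in
#' the lower bin and bins hold approximately equal numbers of reference
#' individuals.
#'
#' @param reference_totals numeric vector of risk-allele totals (>= 8
#'   values)
#' @return integer vector of 3 cutpoints
#' @export
quartile_bins <- function(reference_totals) {
  x <- reference_totals[!is.na(reference_totals)]
  if (length(x) < 8) stop("need at least 8 reference individuals")
  if (length(unique(x)) == 1) stop("degenerate totals: all equal")
  cut <- floor(quantile(x, c(0.25, 0.5, 0.75), type = 1, names = FALSE))
  as.integer(cut)
}

#' Assign totals to quartile bins
#'
#' @param totals numeric vector
#' @param bins cutpoints from [quartile_bins()]
#' @return integer vector of quartile indices 1-4 (`NA` stays `NA`)
#' @export
assign_quartile <- function(totals, bins) {
  findInterval(totals, c(-Inf, bins + 0.5, Inf), left.open = TRUE)
}

#' Bin labels in report style
#' @param bins cutpoints from [quartile_bins()]
#' @return character vector of 4 labels, e.g. `"<=87"`, `"88-91"`, ...
#' @export
quartile_labels <- function(bins) {
  c(paste0("<=", bins[1]),
    paste0(bins[1] + 1, "-", bins[2]),
    paste0(bins[2] + 1, "-", bins[3]),
    paste0(">", bins[3]))
}

#' Quartile-by-cohort summary table with odds ratios
#'
#' Counts reference and cohort individuals per quartile and, for quartiles
#' 2-4, computes the odds ratio against quartile 1 from the 2x2 of
#' (cohort, reference) counts via [two_by_two_or()].  Quartile 1 is the
#' reference row with OR fixed at 1.
#'
#' @param reference_totals,cohort_totals numeric vectors of risk-allele
#'   totals
#' @param bins cutpoints from [quartile_bins()]; computed from
#'   `reference_totals` when omitted
#' @return data.frame with one row per quartile: label, n_reference,
#'   n_cohort, or, ci_low, ci_high, p; the trend test result is attached
#'   as attributes `trend_p` and `trend_slope`
#' @export
quartile_table <- function(reference_totals, cohort_totals, bins = NULL) {
  if (is.null(bins)) bins <- quartile_bins(reference_totals)
  qr <- assign_quartile(reference_totals, bins)
  qc <- assign_quartile(cohort_totals, bins)
  n_ref <- tabulate(qr, 4)
  n_coh <- tabulate(qc, 4)
  res <- two_by_two_or(n_coh[2:4], n_coh[1], n_ref[2:4], n_ref[1])
  out <- data.frame(
    quartile = 1:4,
    label = quartile_labels(bins),
    n_reference = n_ref,
    n_cohort = n_coh,
    or = c(1, res$or),
    ci_low = c(NA, res$ci_low),
    ci_high = c(NA, res$ci_high),
    p = c(NA, res$p))
  tr <- trend_test(reference_totals, cohort_totals, bins)
  attr(out, "trend_p") <- tr$p
  attr(out, "trend_slope") <- tr$slope
  attr(out, "bins") <- bins
  out
}

#' Logistic trend test over quartile index
#'
#' Maximum-likelihood logistic regression of cohort membership (cohort =
#' 1, reference = 0) on the quartile index coded 1, 2, 3, 4 as a single
#' continuous covariate; the p-value is the two-sided Wald test on the
#' slope.
#'
#' @inheritParams quartile_table
#' @return list with `slope`, `se`, `p` and `converged`
#' @export
trend_test <- function(reference_totals, cohort_totals, bins = NULL) {
  if (is.null(bins)) bins <- quartile_bins(reference_totals)
  qr <- assign_quartile(reference_totals, bins)
  qc <- assign_quartile(cohort_totals, bins)
  x <- c(qr, qc)
  y <- c(rep(0L, length(qr)), rep(1L, length(qc)))
  keep <- !is.na(x)
  fit <- suppressWarnings(glm(y[keep] ~ x[keep], family = binomial()))
  sm <- summary(fit)$coefficients
  list(slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       p = unname(sm[2, 4]), converged = fit$converged)
}

#' Quartile table computed directly from printed per-quartile counts
#'
#' Convenience wrapper used when only the aggregated counts (not the
#' individual totals) are available, as when re-deriving a published
#' quartile table: reconstructs individual-level quartile indices from the
#' counts and delegates to [two_by_two_or()] and the trend fit.
#'
#' @param n_reference,n_cohort integer vectors of length 4
#' @param labels optional bin labels
#' @return same shape as [quartile_table()]
#' @export
quartile_table_from_counts <- function(n_reference, n_cohort,
                                       labels = paste0("Q", 1:4)) {
  stopifnot(length(n_reference) == 4, length(n_cohort) == 4)
  res <- two_by_two_or(n_cohort[2:4], n_cohort[1], n_reference[2:4],
                       n_reference[1])
  out <- data.frame(
    quartile = 1:4, label = labels,
    n_reference = n_reference, n_cohort = n_cohort,
    or = c(1, res$or), ci_low = c(NA, res$ci_low),
    ci_high = c(NA, res$ci_high), p = c(NA, res$p))
  x <- c(rep(1:4, n_reference), rep(1:4, n_cohort))
  y <- c(rep(0L, sum(n_reference)), rep(1L, sum(n_cohort)))
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  sm <- summary(fit)$coefficients
  attr(out, "trend_p") <- unname(sm[2, 4])
  attr(out, "trend_slope") <- unname(sm[2, 1])
  out
}
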