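# Variant- and site-level quality control for the sequenced cohort, plus a
# pairwise relatedness check.  Thresholds follow the WGS filtering protocol:
# per-call read depth of at least 5 with a variant QUAL strictly above 20,
# and a site mask requiring depth >= 10 in at least 90% of samples.

#' Per-call depth and per-variant QUAL filter
#'
#' A genotype call with read depth below `min_depth` is set to missing; a
#' variant whose QUAL is not strictly greater than `min_qual` is dropped
#' entirely.  Dosage values are never altered other than to `NA`.
#'
#' @param genotypes a [genotype_matrix()] (individuals x variants)
#' @param depth matrix of read depths aligned to `genotypes`
#' @param qual numeric vector of per-variant QUAL scores
#' @param min_depth minimum per-call depth retained (inclusive)
#' @param min_qual QUAL threshold (exclusive: a variant needs QUAL >
#'   `min_qual` to survive)
#' @return filtered [genotype_matrix()]; dropped variants are removed,
#'   low-depth calls are `NA`
#' @export
variant_qc <- function(genotypes, depth, qual, min_depth = 5, min_qual = 20) {
  if (!all(dim(depth) == dim(genotypes))) {
    stop("depth table (", paste(dim(depth), collapse = "x"),
         ") not aligned to genotypes (",
         paste(dim(genotypes), collapse = "x"), ")")
  }
  if (length(qual) != ncol(genotypes)) {
    stop("qual length ", length(qual), " != ", ncol(genotypes), " variants")
  }
  out <- unclass(genotypes)
  out[depth < min_depth] <- NA_integer_
  keep <- !is.na(qual) & qual > min_qual
  genotype_matrix(out[, keep, drop = FALSE],
                  individual_ids = rownames(genotypes),
                  variant_ids = colnames(genotypes)[keep])
}

#' Site-level callable mask
#'
#' A site is callable when at least `min_fraction` of individuals have
#' depth of at least `min_depth` there.  Monotone in `min_fraction`:
#' raising it never adds sites.
#'
#' @param depth matrix of read depths (individuals x variants)
#' @param min_depth per-call depth cutoff (inclusive)
#' @param min_fraction fraction of individuals required (inclusive)
#' @return logical vector, one entry per variant
#' @export
site_mask <- function(depth, min_depth = 10, min_fraction = 0.9) {
  covered <- colSums(depth >= min_depth) / nrow(depth)
  covered >= min_fraction
}

#' Pairwise genotype concordance between cohort individuals
#'
#' For each pair of individuals, the fraction of co-called variants with
#' identical dosage.  Duplicates and close relatives show up as
#' high-concordance pairs; flagged pairs are reported, not removed.  A
#' pair with no co-called variants gets `NA` concordance and is reported
#' as undefined.
#'
#' @param genotypes a [genotype_matrix()]
#' @param flag_threshold concordance above which a pair is flagged
#' @return list with `concordance` (symmetric matrix, unit diagonal) and
#'   `flagged` (data.frame of pairs with concordance > threshold or
#'   undefined)
#' @export
pairwise_relatedness <- function(genotypes, flag_threshold = 0.9) {
  n <- nrow(genotypes)
  if (n < 2) stop("need at least 2 individuals")
  ids <- rownames(genotypes)
  conc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(conc) <- 1
  flagged <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- !is.na(genotypes[i, ]) & !is.na(genotypes[j, ])
      if (!any(co)) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], n_co_called = 0L,
          concordance = NA_real_, note = "undefined")
        next
      }
      f <- mean(genotypes[i, co] == genotypes[j, co])
      conc[i, j] <- conc[j, i] <- f
      if (f > flag_threshold) {
        flagged[[length(flagged) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j], n_co_called = sum(co),
          concordance = f, note = "high_concordance")
      }
    }
  }
  flagged <- if (length(flagged) > 0) do.call(rbind, flagged) else
    data.frame(id1 = character(), id2 = character(),
               n_co_called = integer(), concordance = numeric(),
               note = character())
  list(concordance = conc, flagged = flagged)
}
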