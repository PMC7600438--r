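# Selection of GWAS risk SNPs: the six exclusion criteria applied to
# published hit lists, with greedy LD pruning against a reference panel.
# Removal reasons:
#   1 unspecified risk allele
#   2 unspecified MAF, or MAF strictly inside (0.45, 0.55)
#   3 published risk-allele OR below 1.04
#   4 subtype-specific association only (ER status / histology)
#   5 absent from the 1000 Genomes reference
#   6 LD pruning: of two or more SNPs with pairwise r^2 > 0.8, one is kept

#' Genotypic LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of alternate-allele dosages over co-called
#' individuals.
#'
#' @param dosage_a,dosage_b equal-length dosage vectors (0/1/2, `NA`
#'   allowed)
#' @return r^2 in `[0,1]`, or `NA` when fewer than 2 co-observations or a
#'   vector has zero variance
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) {
    stop("dosage vectors differ in length")
  }
  co <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(co) < 2) return(NA_real_)
  a <- dosage_a[co]; b <- dosage_b[co]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Pairwise r-squared matrix for a set of SNPs
#'
#' r^2 is only defined within a chromosome; between-chromosome entries are
#' `NA` (and never pruned on).
#'
#' @param genotypes reference [genotype_matrix()] with columns named by
#'   rsid
#' @param snps risk-SNP data.frame (rsid, chrom); defaults to all columns
#' @return symmetric matrix of r^2 with unit diagonal
#' @export
ld_r2_matrix <- function(genotypes, snps = NULL) {
  ids <- if (is.null(snps)) colnames(genotypes) else snps$rsid
  ids <- intersect(ids, colnames(genotypes))
  chrom <- if (is.null(snps)) rep(1L, length(ids)) else
    snps$chrom[match(ids, snps$rsid)]
  k <- length(ids)
  r2 <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(r2) <- 1
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (chrom[i] != chrom[j]) next
        r2[i, j] <- r2[j, i] <- ld_r2(genotypes[, ids[i]], genotypes[, ids[j]])
      }
    }
  }
  r2
}

# Union-find over SNP indices; components of the r2 > threshold graph.
.ld_components <- function(r2, threshold) {
  k <- nrow(r2)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j && !is.na(r2[i, j]) && r2[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(k), find, integer(1))
}

#' Prune SNPs in linkage disequilibrium
#'
#' Linked clusters are the connected components of the graph joining pairs
#' with r^2 strictly above `threshold`; within each cluster exactly one
#' SNP survives: the one with the largest published effect `|ln OR|`
#' (unspecified OR counts as 0), ties broken by lexicographically smallest
#' rsID.  The deterministic tie rule makes the result invariant to input
#' order.
#'
#' @param snps risk-SNP data.frame (rsid, or_published)
#' @param r2 symmetric r^2 matrix with dimnames covering `snps$rsid`
#' @param threshold pruning threshold (strict `>`)
#' @return list with `retained` (subset of `snps`) and `removed`
#'   (data.frame rsid, kept_rsid)
#' @export
prune_ld <- function(snps, r2, threshold = 0.8) {
  if (nrow(snps) == 0) {
    return(list(retained = snps,
                removed = data.frame(rsid = character(),
                                     kept_rsid = character())))
  }
  ord <- order(snps$rsid)  # canonical order: result independent of input order
  s <- snps[ord, , drop = FALSE]
  r2 <- r2[s$rsid, s$rsid, drop = FALSE]
  comp <- .ld_components(r2, threshold)
  effect <- abs(log(ifelse(is.na(s$or_published), 1, s$or_published)))
  keep <- logical(nrow(s))
  removed <- list()
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    best <- members[order(-effect[members], s$rsid[members])][1]
    keep[best] <- TRUE
    losers <- setdiff(members, best)
    if (length(losers) > 0) {
      removed[[length(removed) + 1L]] <- data.frame(
        rsid = s$rsid[losers], kept_rsid = s$rsid[best])
    }
  }
  removed <- if (length(removed) > 0) do.call(rbind, removed) else
    data.frame(rsid = character(), kept_rsid = character())
  retained <- snps[snps$rsid %in% s$rsid[keep], , drop = FALSE]
  list(retained = retained, removed = removed)
}

#' Apply the six risk-SNP exclusion criteria
#'
#' Criteria 1-5 are tested per SNP in order; a removed SNP carries the
#' first matching criterion number.  Criterion 6 (LD pruning via
#' [prune_ld()]) is applied to the survivors, with r^2 estimated from the
#' reference panel genotypes.
#'
#' @param snps risk-SNP data.frame (see [validate_risk_snps()])
#' @param reference_genotypes reference [genotype_matrix()] with columns
#'   named by rsid, used for r^2; SNPs absent from it must already carry
#'   `in_thousand_genomes = FALSE`
#' @param maf_interval open interval of excluded MAFs (criterion 2)
#' @param min_or minimum published OR (criterion 3, strict `<` excludes)
#' @param r2_threshold LD pruning threshold (criterion 6)
#' @return list with `retained` (risk-SNP subset) and `exclusions`
#'   (data.frame rsid, criterion, detail)
#' @export
filter_risk_snps <- function(snps, reference_genotypes = NULL,
                             maf_interval = c(0.45, 0.55), min_or = 1.04,
                             r2_threshold = 0.8) {
  validate_risk_snps(snps)
  reason <- rep(NA_integer_, nrow(snps))
  detail <- rep(NA_character_, nrow(snps))
  mark <- function(cond, criterion, msg) {
    cond[is.na(cond)] <- FALSE
    hit <- cond & is.na(reason)
    reason[hit] <<- criterion
    detail[hit] <<- msg
  }
  mark(is.na(snps$risk_allele) | snps$risk_allele == "", 1L,
       "unspecified risk allele")
  mark(is.na(snps$maf), 2L, "unspecified MAF")
  mark(snps$maf > maf_interval[1] & snps$maf < maf_interval[2], 2L,
       sprintf("MAF in (%.2f, %.2f)", maf_interval[1], maf_interval[2]))
  mark(is.na(snps$or_published) | snps$or_published < min_or, 3L,
       sprintf("OR below %.2f", min_or))
  mark(snps$subtype_specific, 4L, "subtype-specific association only")
  mark(!snps$in_thousand_genomes, 5L, "absent from 1000 Genomes")

  survivors <- snps[is.na(reason), , drop = FALSE]
  if (nrow(survivors) > 1 && !is.null(reference_genotypes)) {
    r2 <- ld_r2_matrix(reference_genotypes, survivors)
    present <- survivors$rsid %in% rownames(r2)
    pruned <- prune_ld(survivors[present, , drop = FALSE],
                       r2, threshold = r2_threshold)
    dropped <- pruned$removed
    if (nrow(dropped) > 0) {
      idx <- match(dropped$rsid, snps$rsid)
      reason[idx] <- 6L
      detail[idx] <- paste0("in LD with retained ", dropped$kept_rsid)
    }
  }
  exclusions <- data.frame(rsid = snps$rsid, criterion = reason,
                           detail = detail)[!is.na(reason), , drop = FALSE]
  list(retained = snps[is.na(reason), , drop = FALSE],
       exclusions = exclusions)
}
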