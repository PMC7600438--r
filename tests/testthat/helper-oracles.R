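# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package implementation.

# Odds ratio for a 2x2 allele table via an iteratively fitted logistic
# model (IRLS through stats::glm), the reference route for two_by_two_or.
irls_or_oracle <- function(a, b, c, d) {
  dat <- data.frame(y = c(1, 1, 0, 0), x = c(1, 0, 1, 0),
                    w = c(a, b, c, d))
  fit <- suppressWarnings(glm(y ~ x, family = binomial(), data = dat,
                              weights = w,
                              control = glm.control(epsilon = 1e-14)))
  sm <- summary(fit)$coefficients
  list(or = exp(unname(coef(fit)[2])), p = unname(sm[2, 4]),
       se = unname(sm[2, 2]))
}

# Connected components of the r2 > threshold graph by boolean matrix
# powers (transitive closure), independent of the union-find in the
# package.
reachability_components <- function(r2, threshold) {
  k <- nrow(r2)
  adj <- !is.na(r2) & r2 > threshold
  diag(adj) <- TRUE
  reach <- adj
  for (step in seq_len(k)) reach <- (reach %*% adj) > 0
  comp <- integer(k)
  next_id <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[reach[i, ]] <- next_id
    }
  }
  comp
}

# Exhaustive-search LD pruning oracle: enumerate all subsets, keep those
# with no linked pair and exactly one member per component, then pick the
# subset matching the max-|ln OR| / smallest-rsid representative rule.
brute_force_prune <- function(snps, r2, threshold) {
  k <- nrow(snps)
  comp <- reachability_components(r2[snps$rsid, snps$rsid, drop = FALSE],
                                  threshold)
  effect <- abs(log(ifelse(is.na(snps$or_published), 1, snps$or_published)))
  best <- character(0)
  for (cp in unique(comp)) {
    members <- which(comp == cp)
    ord <- members[order(-effect[members], snps$rsid[members])]
    best <- c(best, snps$rsid[ord[1]])
  }
  sort(best)
}

# Toy VCF text used by the IO tests: 3 samples, 2 sites, one missing
# genotype and one multi-allelic record.
toy_vcf_lines <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "101", "rs1", "A", "G", "50", "PASS", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("2", "202", "rs2", "C", "T,G", "60", "PASS", ".", "GT",
          "0/2", "1/2", "0/0", sep = "\t"))
}
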