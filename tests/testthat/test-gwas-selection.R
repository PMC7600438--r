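mk_snps <- function(rsid, or = 1.2, maf = 0.3, chrom = "1") {
  n <- length(rsid)
  data.frame(rsid = rsid, cancer_type = "BC", chrom = chrom,
             pos = seq_len(n), risk_allele = "A", maf = maf,
             or_published = or, subtype_specific = FALSE,
             in_thousand_genomes = TRUE)
}

test_that("ld_r2 is squared Pearson correlation over co-called dosages", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(ld_r2(a, a), 1)
  # hand-evaluated Pearson: cov 3, variances 4 and 4 -> r2 = 9/16
  expect_equal(ld_r2(a, c(0, 1, 0, 1, 2, 2)), 9 / 16)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))  # zero variance
  expect_true(is.na(ld_r2(c(0, NA, NA), c(0, NA, NA))))  # < 2 co-called
  expect_error(ld_r2(1:3, 1:4), "length")
  # missing entries are dropped pairwise, not imputed
  expect_equal(ld_r2(c(a, 0, NA), c(0, 1, 0, 1, 2, 2, NA, 1)), 9 / 16)
})

test_that("independent loci have mean r2 near 1/n", {
  set.seed(13)
  n <- 500
  r2 <- replicate(300, ld_r2(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3)))
  expect_equal(mean(r2), 1 / n, tolerance = 0.3)  # relative MC tolerance
})

test_that("prune_ld keeps the strongest-effect SNP of a linked pair", {
  snps <- mk_snps(c("rsA", "rsB"), or = c(1.10, 1.20))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(snps$rsid, snps$rsid))
  res <- prune_ld(snps, r2)
  expect_equal(res$retained$rsid, "rsB")
  expect_equal(res$removed$rsid, "rsA")

  # r2 exactly at the threshold is not linked (strict >)
  r2[1, 2] <- r2[2, 1] <- 0.8
  expect_equal(nrow(prune_ld(snps, r2)$retained), 2L)

  # protective alleles compete on |ln OR|
  snps2 <- mk_snps(c("rsA", "rsB"), or = c(0.5, 1.5))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(snps2$rsid, snps2$rsid))
  expect_equal(prune_ld(snps2, r2)$retained$rsid, "rsA")  # |ln 0.5| > ln 1.5

  # ties break to the lexicographically smallest rsid
  snps3 <- mk_snps(c("rsB", "rsA"), or = c(1.2, 1.2))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(snps3$rsid, snps3$rsid))
  expect_equal(prune_ld(snps3, r2)$retained$rsid, "rsA")
})

test_that("prune_ld matches the exhaustive-search oracle on small instances", {
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(3:8, 1)
    snps <- mk_snps(sprintf("rs%02d", sample(99, k)),
                    or = round(exp(rnorm(k, 0, 0.2)), 3))
    r2 <- matrix(0, k, k, dimnames = list(snps$rsid, snps$rsid))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r2[i, j] <- r2[j, i] <- sample(c(0.05, 0.5, 0.85, 0.95), 1)
    }
    diag(r2) <- 1
    got <- sort(prune_ld(snps, r2)$retained$rsid)
    expect_equal(got, brute_force_prune(snps, r2, 0.8))
    # input-order invariance
    perm <- sample(k)
    expect_equal(sort(prune_ld(snps[perm, ], r2)$retained$rsid), got)
  }
})

test_that("a 5-SNP chain with alternating r2 prunes like the oracle", {
  snps <- mk_snps(sprintf("rs%d", 1:5), or = c(1.3, 1.1, 1.25, 1.05, 1.15))
  r2 <- diag(5)
  dimnames(r2) <- list(snps$rsid, snps$rsid)
  links <- c(0.9, 0.5, 0.95, 0.6)  # chain 1-2, 2-3, 3-4, 4-5
  for (i in 1:4) r2[i, i + 1] <- r2[i + 1, i] <- links[i]
  got <- sort(prune_ld(snps, r2)$retained$rsid)
  expect_equal(got, brute_force_prune(snps, r2, 0.8))
  expect_equal(got, sort(c("rs1", "rs3", "rs5")))
})

test_that("the six exclusion criteria each fire once on a constructed list", {
  snps <- mk_snps(sprintf("rs%d", 1:7))
  snps$risk_allele[1] <- NA            # 1: unspecified risk allele
  snps$maf[2] <- 0.50                  # 2: MAF inside (0.45, 0.55)
  snps$or_published[3] <- 1.03         # 3: OR below 1.04
  snps$subtype_specific[4] <- TRUE     # 4: subtype-specific only
  snps$in_thousand_genomes[5] <- FALSE # 5: absent from 1000 Genomes
  set.seed(3)
  base <- rbinom(200, 2, 0.3)
  ref <- genotype_matrix(cbind(base, base, base, base, base, base,
                               rbinom(200, 2, 0.3)),
                         variant_ids = snps$rsid)
  # rs6 is in perfect LD with rs7's survivor set companion: rs6 and rs7
  # compete; rs6 shares the template with the earlier excluded SNPs, so
  # the surviving linked pair is (rs6 = template copy, rs7 independent)
  res <- filter_risk_snps(snps, ref)
  expect_equal(sort(unique(res$exclusions$criterion)), 1:5)
  expect_equal(sort(res$retained$rsid), c("rs6", "rs7"))

  # now force criterion 6: make rs7 a copy of the template too
  ref2 <- genotype_matrix(cbind(base, base, base, base, base, base, base),
                          variant_ids = snps$rsid)
  res2 <- filter_risk_snps(snps, ref2)
  expect_equal(sort(unique(res2$exclusions$criterion)), 1:6)
  expect_equal(nrow(res2$retained), 1L)
  # retained + removed partition the input
  expect_equal(nrow(res2$retained) + nrow(res2$exclusions), nrow(snps))
  expect_false(any(res2$retained$rsid %in% res2$exclusions$rsid))
})

test_that("criterion boundaries: MAF 0.45 retained, OR 1.04 retained", {
  snps <- mk_snps(c("rs1", "rs2", "rs3"), maf = c(0.45, 0.55, 0.3),
                  or = c(1.2, 1.2, 1.04))
  res <- filter_risk_snps(snps)
  expect_equal(nrow(res$retained), 3L)  # open interval, non-strict OR cut
  snps$maf[1] <- 0.4501
  expect_equal(filter_risk_snps(snps)$exclusions$criterion, 2L)
})

test_that("each removal carries the first matching criterion", {
  snps <- mk_snps("rs1")
  snps$risk_allele <- NA
  snps$maf <- NA  # trips 1 and 2; reason must be 1
  expect_equal(filter_risk_snps(snps)$exclusions$criterion, 1L)
  expect_error(filter_risk_snps(rbind(mk_snps("rs1"), mk_snps("rs1"))),
               "duplicate")
})

test_that("filtering is idempotent on generated panels", {
  gp <- gen_risk_snp_panel(106, c(rep("keep", 10), "bad_maf", "low_or",
                                  "keep", "ld_duplicate"),
                           seed = 31)
  first <- filter_risk_snps(gp$snps, gp$reference_genotypes)
  again <- filter_risk_snps(first$retained, gp$reference_genotypes)
  expect_equal(nrow(again$exclusions), 0L)
  expect_equal(again$retained$rsid, first$retained$rsid)
})
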