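test_that("carrier_freq implements (AC - Hom) / (AN / 2)", {
  expect_equal(carrier_freq(3, 1, 100), 0.04)
  expect_equal(carrier_freq(0, 0, 100), 0)
  expect_error(carrier_freq(1, 0, 0), "positive")
  # HWE simulation: carrier fraction approaches 1 - (1-f)^2
  sites <- gen_reference_sites(1e4, 0.01, seed = 73)
  q <- carrier_freq(sites$ac, sites$hom, sites$an)
  expect_equal(q, 1 - 0.99^2, tolerance = 0.25)
})

test_that("carrier_probability aggregates independent sites", {
  expect_equal(carrier_probability(c(0.5, 0.5)), 0.75)
  expect_equal(carrier_probability(0.123), 0.123)
  expect_warning(p0 <- carrier_probability(numeric(0)), "k = 0")
  expect_equal(p0, 0)
  expect_error(carrier_probability(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("carrier_probability matches a large Monte-Carlo simulation", {
  set.seed(79)
  q <- runif(20, 0.001, 0.05)
  p_closed <- carrier_probability(q)
  n_draws <- 1e5
  carries <- rowSums(matrix(runif(n_draws * 20) <
                              rep(q, each = n_draws), n_draws)) > 0
  p_sim <- mean(carries)
  mc_se <- sqrt(p_closed * (1 - p_closed) / n_draws)
  expect_lt(abs(p_closed - p_sim), 3 * mc_se)
})

test_that("carrier_probability is monotone and union-bounded", {
  set.seed(83)
  for (rep in 1:20) {
    q <- runif(sample(2:30, 1), 0, 0.2)
    p <- carrier_probability(q)
    expect_lte(p, sum(q))
    expect_gte(p, max(q))
    bumped <- q
    i <- sample(length(q), 1)
    bumped[i] <- min(1, bumped[i] + 0.1)
    expect_gte(carrier_probability(bumped), p)
  }
})

test_that("cohort carrier probability is the observed carrier fraction", {
  dos <- matrix(0L, 51, 3)
  dos[1, 1] <- 1L; dos[2, 2] <- 2L; dos[3, 3] <- 1L
  gm <- genotype_matrix(dos)
  res <- cohort_carrier_probability(gm)
  expect_equal(res$p, 3 / 51)
  expect_equal(sum(res$indicators), 3L)
  expect_equal(cohort_carrier_probability(gm, character(0))$p, 0)
  all_carry <- genotype_matrix(matrix(1L, 5, 2))
  expect_equal(cohort_carrier_probability(all_carry)$p, 1)
  # missing dosages count as non-carriage
  dos[1, 1] <- NA
  expect_equal(cohort_carrier_probability(genotype_matrix(dos))$p, 2 / 51)
  expect_error(cohort_carrier_probability(gm[0, , drop = FALSE]),
               "zero individuals")
})

test_that("carrier_or follows the odds-ratio identity and its boundaries", {
  expect_equal(carrier_or(0.5, 0.5), 1)
  expect_equal(carrier_or(0.75, 0.5), 3)
  expect_equal(carrier_or(0.06, 0.15), 0.361702, tolerance = 1e-6)
  expect_equal(carrier_or(0, 0.5), 0)
  expect_equal(carrier_or(1, 0.5), Inf)
  expect_true(is.na(carrier_or(0.5, 0)))
  set.seed(89)
  for (rep in 1:20) {
    p <- runif(2, 0.01, 0.99)
    expect_equal(carrier_or(p[1], p[2]) * carrier_or(p[2], p[1]), 1)
  }
})

test_that("BCa intervals are seed-reproducible and handle degeneracy", {
  ind <- c(rep(1L, 8), rep(0L, 43))
  a <- bca_ci(ind, 0.2, n_boot = 2000, seed = 11)
  b <- bca_ci(ind, 0.2, n_boot = 2000, seed = 11)
  expect_identical(a[c("ci_low", "ci_high", "z0", "accel")],
                   b[c("ci_low", "ci_high", "z0", "accel")])
  expect_true(a$ci_low <= a$or && a$or <= a$ci_high)

  # all indicators identical: interval collapses to the point estimate
  deg <- bca_ci(rep(1L, 51), 0.2, n_boot = 2000, seed = 11)
  expect_true(deg$degenerate)
  expect_equal(deg$ci_low, deg$ci_high)
  expect_error(bca_ci(ind, 0.2, n_boot = 100, seed = 1), "1000")
  expect_error(bca_ci(ind, 0, n_boot = 2000, seed = 1), "inside")
  expect_error(bca_ci(ind, 0.2, n_boot = 2000), "seed")
})

test_that("with no bias or acceleration BCa reduces to plain percentiles", {
  ind <- c(rep(1L, 8), rep(0L, 43))
  res <- bca_ci(ind, 0.2, n_boot = 5000, seed = 13)
  # recompute the adjusted percentile mapping from the returned pieces:
  # at z0 = 0 and a = 0 it must hand back exactly (0.025, 0.975)
  z <- qnorm(c(0.025, 0.975))
  expect_equal(pnorm(0 + (0 + z) / (1 - 0 * (0 + z))), c(0.025, 0.975))
  # and the reported interval equals type-1 quantiles of the replicates
  # at the mapped levels computed from the reported z0 and accel
  a1 <- pnorm(res$z0 + (res$z0 + z[1]) / (1 - res$accel * (res$z0 + z[1])))
  a2 <- pnorm(res$z0 + (res$z0 + z[2]) / (1 - res$accel * (res$z0 + z[2])))
  expect_equal(unname(quantile(res$replicates, c(a1, a2), type = 1)),
               c(res$ci_low, res$ci_high))
})

test_that("BCa endpoints agree with the boot-package implementation", {
  skip_if_not_installed("boot")
  cases <- list(c(k = 3, p_ref = 0.15), c(k = 13, p_ref = 0.1167),
                c(k = 30, p_ref = 0.5))
  for (cs in cases) {
    ind <- c(rep(1L, cs[["k"]]), rep(0L, 51 - cs[["k"]]))
    mine <- bca_ci(ind, cs[["p_ref"]], n_boot = 10000, seed = 17)
    set.seed(18)
    bt <- boot::boot(ind, function(d, i) {
      p <- mean(d[i])
      (p * (1 - cs[["p_ref"]])) / ((1 - p) * cs[["p_ref"]])
    }, R = 10000)
    ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
    # two independent resample sets: agreement to quantile-grid resolution
    expect_equal(mine$ci_low, ref[1], tolerance = 0.08)
    expect_equal(mine$ci_high, ref[2], tolerance = 0.08)
  }
})

test_that("carrier_report assembles planted scenarios faithfully", {
  sites <- gen_reference_sites(5000, runif(30, 5e-4, 5e-3), seed = 97)
  q <- carrier_freq(sites$ac, sites$hom, sites$an)
  scen <- list(
    planted = list(cohort_indicators = c(rep(1L, 10), rep(0L, 41)),
                   n_cohort_variants = 12, reference_q = q),
    empty = list(cohort_indicators = rep(0L, 51),
                 n_cohort_variants = 0, reference_q = q))
  rep_tab <- carrier_report(scen, n_boot = 2000, seed = 5)
  expect_equal(rep_tab$p_reference[1], carrier_probability(q))
  expect_equal(rep_tab$p_cohort[1], 10 / 51)
  expect_equal(rep_tab$p_cohort_pct[1], "20 %")
  # zero cohort carriers: probabilities reported, OR omitted
  expect_equal(rep_tab$p_cohort[2], 0)
  expect_true(is.na(rep_tab$or[2]))
})

test_that("identical cohort and reference probabilities give OR near 1", {
  set.seed(101)
  ors <- replicate(40, {
    ind <- rbinom(51, 1, 0.3)
    carrier_or(mean(ind), 0.3)
  })
  expect_equal(mean(log(ors[is.finite(ors) & ors > 0])), 0, tolerance = 0.15)
})
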