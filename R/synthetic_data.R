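# Synthetic-data generators: every input the pipeline consumes, with the
# statistical structure the analysis assumes.  Sites are independent
# Hardy-Weinberg draws (matching the independence assumption of the
# carrier-probability formula) except for explicitly planted LD blocks.
# All generators are pure functions of (parameters, seed).  Default
# scales mirror the study design: a 51-individual sequenced cohort, a
# 294-individual reference panel for quartile binning, and site counts on
# a 33,370-individual exome-reference scale.

#' Simulate a cohort genotype matrix under Hardy-Weinberg equilibrium
#'
#' Dosages are independent Binomial(2, f) draws per site.  Optionally
#' attaches a read-depth table and per-variant QUAL scores with planted
#' low-depth / low-QUAL contamination for exercising the QC stage.
#'
#' @param n_individuals cohort size
#' @param site_freqs per-site alternate/risk allele frequencies in `[0,1]`
#' @param seed integer seed
#' @param depth when `TRUE`, also simulate depths (Poisson around
#'   `mean_depth`) and QUALs
#' @param mean_depth mean simulated read depth
#' @param low_depth_rate fraction of calls forced to depth below 5
#' @param n_low_qual number of variants given QUAL below 20
#' @return list with `genotypes` ([genotype_matrix()]), `variants`
#'   (chrom/pos/ref/alt/qual data.frame) and, when `depth = TRUE`,
#'   `depth` (matrix)
#' @export
gen_cohort <- function(n_individuals, site_freqs, seed, depth = FALSE,
                       mean_depth = 42, low_depth_rate = 0,
                       n_low_qual = 0) {
  stopifnot(all(site_freqs >= 0 & site_freqs <= 1))
  set.seed(seed)
  m <- length(site_freqs)
  dos <- matrix(rbinom(n_individuals * m, 2L,
                       rep(site_freqs, each = n_individuals)),
                nrow = n_individuals, ncol = m)
  variants <- data.frame(
    chrom = rep("1", m), pos = seq_len(m) * 100L,
    ref = rep("A", m), alt = rep("G", m),
    qual = rep(60, m))
  if (n_low_qual > 0) {
    variants$qual[sample.int(m, min(n_low_qual, m))] <- 15
  }
  gm <- genotype_matrix(dos,
                        individual_ids = sprintf("ind%03d", seq_len(n_individuals)),
                        variant_ids = variant_key(variants$chrom, variants$pos,
                                                  variants$ref, variants$alt))
  out <- list(genotypes = gm, variants = variants)
  if (depth) {
    dp <- matrix(stats::rpois(n_individuals * m, mean_depth),
                 nrow = n_individuals, ncol = m)
    if (low_depth_rate > 0) {
      low <- runif(n_individuals * m) < low_depth_rate
      dp[low] <- sample(0:4, sum(low), replace = TRUE)
    }
    dimnames(dp) <- dimnames(gm)
    out$depth <- dp
  }
  out
}

#' Simulate an ExAC-style reference site-count table
#'
#' Latent genotypes for `n_individuals` are drawn under Hardy-Weinberg
#' equilibrium at each site and tabulated into (AC, Hom, AN) triples,
#' which therefore satisfy the site-count invariants by construction.
#' The latent carrier count (AC - Hom) is retained for identity checks.
#'
#' @param n_individuals reference population size
#' @param site_freqs per-site allele frequencies
#' @param seed integer seed
#' @param genes optional per-site gene symbols carried through
#' @return site-count data.frame (chrom, pos, ref, alt, ac, hom, an, gene)
#'   with the latent per-site carrier counts in `attr(, "carriers")`
#' @export
gen_reference_sites <- function(n_individuals, site_freqs, seed,
                                genes = NULL) {
  stopifnot(all(site_freqs >= 0 & site_freqs <= 1))
  set.seed(seed)
  m <- length(site_freqs)
  ac <- hom <- carriers <- integer(m)
  for (i in seq_len(m)) {
    g <- rbinom(n_individuals, 2L, site_freqs[i])
    ac[i] <- sum(g)
    hom[i] <- sum(g == 2L)
    carriers[i] <- sum(g > 0L)
  }
  out <- data.frame(
    chrom = rep("1", m), pos = seq_len(m) * 100L,
    ref = rep("A", m), alt = rep("G", m),
    ac = ac, hom = hom, an = rep(2L * n_individuals, m))
  if (!is.null(genes)) out$gene <- genes
  attr(out, "carriers") <- carriers
  out
}

#' Generate annotated variants realizing named filter-stage profiles
#'
#' Each variant gets a target profile: `"all_pass"` or `"fail_<stage>"`
#' for exactly one of the cascade stages (`maf`, `cadd`, `conservation`,
#' `deleteriousness`).  Scores are drawn just inside or outside each
#' threshold (MAF around 1e-3, CADD around 10, conservation around the
#' 2-of-3 vote, predictor calls around the strict majority) so the
#' cascade's verdict on the variant is forced, and the ground-truth
#' profile is stored in the `profile` column.
#'
#' @param n number of variants
#' @param stage_fail_mix character vector recycled to length `n` over
#'   `{"all_pass", "fail_maf", "fail_cadd", "fail_conservation",
#'   "fail_deleteriousness"}`
#' @param seed integer seed
#' @param genes gene symbols to draw from
#' @param consequence consequence class assigned to all variants
#' @return annotated-variant data.frame with a `profile` column
#' @export
gen_annotated_variants <- function(n, stage_fail_mix = "all_pass", seed,
                                   genes = sprintf("GENE%02d", 1:20),
                                   consequence = "missense") {
  profiles <- c("all_pass", "fail_maf", "fail_cadd", "fail_conservation",
                "fail_deleteriousness")
  mix <- rep_len(stage_fail_mix, n)
  if (!all(mix %in% profiles)) {
    stop("infeasible profile: ",
         paste(setdiff(unique(mix), profiles), collapse = ", "))
  }
  set.seed(seed)
  x <- data.frame(
    chrom = sample(as.character(1:22), n, replace = TRUE),
    pos = sample.int(1e8, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    gene = sample(genes, n, replace = TRUE),
    consequence = rep(consequence, n),
    rsid = sprintf("rs%07d", sample.int(1e7, n)),
    profile = mix)
  # rarity: pass draws sit well under 1e-3 in every source, fail draws
  # push one source just above it
  x$maf_thousand_genomes <- runif(n, 1e-5, 5e-4)
  x$maf_exac_nfe_nontcga <- runif(n, 1e-5, 5e-4)
  x$maf_local <- runif(n, 0, 4e-4)
  fail <- mix == "fail_maf"
  x$maf_exac_nfe_nontcga[fail] <- runif(sum(fail), 2e-3, 1e-2)
  x$cadd_phred <- runif(n, 15, 40)
  fail <- mix == "fail_cadd"
  x$cadd_phred[fail] <- runif(sum(fail), 0, 9.5)
  # conservation: pass = all three tools vote, fail = at most one
  x$gerp <- runif(n, 2.5, 6); x$phastcons <- runif(n, 0.5, 1)
  x$phylop <- runif(n, 3, 8)
  fail <- mix == "fail_conservation"
  x$gerp[fail] <- runif(sum(fail), -2, 1.5)
  x$phastcons[fail] <- runif(sum(fail), 0, 0.25)
  x$phylop[fail] <- runif(sum(fail), -1, 2.5)
  # deleteriousness: pass = 7-10 of 10 tools, fail = 3-5 of 10
  n_del <- ifelse(mix == "fail_deleteriousness",
                  sample(3:5, n, replace = TRUE),
                  sample(7:10, n, replace = TRUE))
  for (t in seq_along(PREDICTOR_TOOLS)) {
    x[[paste0("pred_", PREDICTOR_TOOLS[t])]] <-
      ifelse(t <= n_del, "deleterious", "tolerated")
  }
  x$intol_esp <- x$intol_exac <- x$intol_local <- x$mis_z <- NA_real_
  x$clinvar_raw <- NA_character_
  x$clinvar <- rep("absent", n)
  validate_annotated_variants(x)
  x
}

#' Generate a risk-SNP panel with planted exclusions and LD blocks
#'
#' Builds a GWAS-style risk-SNP list in which each SNP either survives
#' all exclusion criteria (`"keep"`) or is planted to trip exactly one of
#' them, together with a reference genotype panel for LD estimation.  LD
#' blocks are planted by copying a template dosage vector with per-
#' individual flip noise: a copy that replaces each individual's dosage
#' with a fresh Hardy-Weinberg draw with probability `eps` has expected
#' r^2 of about `(1 - eps)^2`, so `eps = 0.02` lands safely above the 0.8
#' pruning threshold while independent draws land near `1/n`.
#'
#' @param n number of SNPs
#' @param exclusion_mix character vector recycled over `{"keep",
#'   "no_risk_allele", "bad_maf", "low_or", "subtype_only", "not_in_1kg",
#'   "ld_duplicate"}`; each `"ld_duplicate"` SNP is planted in tight LD
#'   with the previous non-duplicate SNP
#' @param n_reference reference panel size for the genotype matrix
#' @param seed integer seed
#' @param eps flip-noise rate inside planted LD blocks
#' @return list with `snps` (risk-SNP data.frame including the
#'   ground-truth `plant` column) and `reference_genotypes`
#'   ([genotype_matrix()] with columns named by rsid)
#' @export
gen_risk_snp_panel <- function(n, exclusion_mix = "keep", n_reference = 294,
                               seed, eps = 0.02) {
  plants <- c("keep", "no_risk_allele", "bad_maf", "low_or", "subtype_only",
              "not_in_1kg", "ld_duplicate")
  mix <- rep_len(exclusion_mix, n)
  if (!all(mix %in% plants)) {
    stop("unknown plant: ", paste(setdiff(unique(mix), plants), collapse = ", "))
  }
  if (mix[1] == "ld_duplicate") stop("first SNP cannot be an LD duplicate")
  set.seed(seed)
  maf <- runif(n, 0.1, 0.4)
  maf[mix == "bad_maf"] <- runif(sum(mix == "bad_maf"), 0.46, 0.54)
  or <- exp(runif(n, log(1.05), log(1.3)))
  or[mix == "low_or"] <- runif(sum(mix == "low_or"), 1.00, 1.035)
  # an LD duplicate carries a weaker effect than its template, so pruning
  # deterministically removes the duplicate
  last_keep <- NA_real_
  for (i in seq_len(n)) {
    if (mix[i] == "ld_duplicate") or[i] <- 1 + (last_keep - 1) / 2
    else last_keep <- or[i]
  }
  snps <- data.frame(
    rsid = sprintf("rs%06d", seq_len(n) * 7 + 1000),
    cancer_type = sample(c("BC", "CRC", "PC"), n, replace = TRUE),
    chrom = rep("1", n),
    pos = seq_len(n) * 1000L,
    risk_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    maf = maf,
    or_published = or,
    subtype_specific = mix == "subtype_only",
    in_thousand_genomes = mix != "not_in_1kg",
    plant = mix)
  snps$risk_allele[mix == "no_risk_allele"] <- NA_character_
  dos <- matrix(0L, n_reference, n)
  template <- NULL
  for (i in seq_len(n)) {
    if (mix[i] == "ld_duplicate") {
      flip <- runif(n_reference) < eps
      dos[, i] <- ifelse(flip, rbinom(n_reference, 2L, maf[i]), template)
    } else {
      dos[, i] <- rbinom(n_reference, 2L, maf[i])
      template <- dos[, i]
    }
  }
  ref <- genotype_matrix(dos,
                         individual_ids = sprintf("ref%04d", seq_len(n_reference)),
                         variant_ids = snps$rsid)
  list(snps = snps, reference_genotypes = ref)
}

#' Generate a paired burden scenario with a known quartile effect
#'
#' Simulates risk-allele totals for a pool of individuals from a
#' discretized normal, bins the pool into quartiles with the same
#' floored-percentile rule the analysis applies ([quartile_bins()]), and
#' draws cohort membership per individual as Bernoulli with the
#' quartile's probability from `effect_profile`.  Non-members form the
#' reference totals.  Because membership log-odds are exactly linear in
#' quartile index when the profile doubles the odds per quartile, the
#' logistic trend slope is recoverable; the cutpoints are returned as
#' ground truth.
#'
#' @param effect_profile length-4 vector of per-quartile cohort-membership
#'   probabilities
#' @param n_per_quartile pool individuals per quartile
#' @param seed integer seed
#' @param mean_total,sd_total discretized-normal parameters for the totals
#' @return list with `reference_totals`, `cohort_totals`, `bins` (the
#'   rank-based cutpoints) and `truth` (the profile and its log-odds
#'   slope between adjacent quartiles)
#' @export
gen_burden_scenario <- function(effect_profile, n_per_quartile, seed,
                                mean_total = 92, sd_total = 6) {
  stopifnot(length(effect_profile) == 4,
            all(effect_profile >= 0 & effect_profile <= 1))
  set.seed(seed)
  n <- 4L * n_per_quartile
  totals <- round(rnorm(n, mean_total, sd_total))
  bins <- quartile_bins(totals)
  quart <- assign_quartile(totals, bins)
  member <- rbinom(n, 1L, effect_profile[quart])
  odds <- effect_profile / (1 - effect_profile)
  list(reference_totals = totals[member == 0],
       cohort_totals = totals[member == 1],
       bins = bins,
       truth = list(profile = effect_profile,
                    log_odds_step = diff(log(odds))))
}
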