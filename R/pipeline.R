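# Stage orchestration: a single configuration drives simulation and the
# seven analysis stages over a shared workspace directory.  Every stage
# reads its inputs from the workspace, writes TSV reports whose headers
# echo the configuration hash and seed, and derives its own RNG stream
# from the master seed, so a rerun with the same configuration is
# byte-identical.

PIPELINE_STAGES <- c("simulate", "qc", "select_snps", "allele_scan",
                     "burden", "prioritize", "carrier", "highrisk")

#' Default pipeline configuration
#'
#' Scales mirror the study design this pipeline re-implements: a
#' 51-individual sequenced cohort, a 294-individual reference panel for
#' quartile binning, an exome reference of 33,370 individuals behind the
#' site-count tables, GWAS panels of 106/81/105 SNPs for breast,
#' colorectal and prostate cancer, and bootstrap settings B = 10,000.
#'
#' @param seed master seed; each stage derives its own stream from it
#' @return nested configuration list
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      n_cohort = 51, n_reference_panel = 294, n_reference_exome = 33370,
      n_snps = c(BC = 106, CRC = 81, PC = 105),
      n_rare_variants = 120, n_reference_sites_per_class = 60,
      mean_depth = 42, low_depth_rate = 0.01, n_low_qual = 5),
    qc = list(min_depth = 5, min_qual = 20, site_min_depth = 10,
              site_min_fraction = 0.9, relatedness_flag = 0.9),
    select_snps = list(maf_interval = c(0.45, 0.55), min_or = 1.04,
                       r2_threshold = 0.8),
    allele_scan = list(alpha = 0.05),
    burden = list(missing = "impute"),
    prioritize = list(maf_threshold = 0.001, cadd_threshold = 10,
                      strict_missing = FALSE),
    carrier = list(n_boot = 10000),
    highrisk = list(maf_threshold = 0.001, freq_source = "thousand_genomes")
  )
}

# Per-stage deterministic sub-seed (kept below 2^31).
.stage_seed <- function(config, stage) {
  (config$seed * 97L + match(stage, PIPELINE_STAGES) * 1009L) %% 2147483647L
}

.ws <- function(workspace, ...) file.path(workspace, ...)

#' Run one pipeline stage
#'
#' @param stage one of `simulate`, `qc`, `select_snps`, `allele_scan`,
#'   `burden`, `prioritize`, `carrier`, `highrisk`
#' @param workspace directory shared between stages
#' @param config configuration list from [default_config()]
#' @return invisible list of written report paths
#' @export
run_stage <- function(stage, workspace, config = default_config()) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  if (!dir.exists(workspace)) dir.create(workspace, recursive = TRUE)
  fun <- switch(stage,
                simulate = .stage_simulate, qc = .stage_qc,
                select_snps = .stage_select_snps,
                allele_scan = .stage_allele_scan, burden = .stage_burden,
                prioritize = .stage_prioritize, carrier = .stage_carrier,
                highrisk = .stage_highrisk)
  invisible(fun(workspace, config))
}

#' Run the full pipeline
#'
#' Chains all stages over the workspace.
#' @inheritParams run_stage
#' @return invisible named list of report paths per stage
#' @export
run_pipeline <- function(workspace, config = default_config()) {
  out <- lapply(PIPELINE_STAGES, run_stage, workspace = workspace,
                config = config)
  names(out) <- PIPELINE_STAGES
  invisible(out)
}

# -- simulate -----------------------------------------------------------

.stage_simulate <- function(workspace, config) {
  sc <- config$simulate
  seed <- .stage_seed(config, "simulate")

  # GWAS risk-SNP panels per cancer type, with a few planted exclusions
  plants <- c(rep("keep", 12), "no_risk_allele", "bad_maf", "low_or",
              "subtype_only", "not_in_1kg", "keep", "ld_duplicate")
  snps <- list(); panels <- list()
  for (i in seq_along(sc$n_snps)) {
    ct <- names(sc$n_snps)[i]
    gp <- gen_risk_snp_panel(sc$n_snps[[i]], exclusion_mix = plants,
                             n_reference = sc$n_reference_panel,
                             seed = seed + i)
    gp$snps$cancer_type <- ct
    gp$snps$rsid <- sprintf("rs%s%05d", ct, seq_len(nrow(gp$snps)))
    colnames(gp$reference_genotypes) <- gp$snps$rsid
    snps[[ct]] <- gp$snps
    panels[[ct]] <- gp$reference_genotypes
  }
  risk_snps <- do.call(rbind, snps)
  rownames(risk_snps) <- NULL
  write_risk_snps(risk_snps, .ws(workspace, "risk_snps.tsv"))

  ref_panel <- do.call(cbind, lapply(panels, unclass))
  utils::write.table(
    data.frame(individual = rownames(panels[[1]]), ref_panel,
               check.names = FALSE),
    .ws(workspace, "reference_panel.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # large-reference risk-allele frequencies (gnomAD-style AF/AN export);
  # the cohort is drawn from the same frequencies, i.e. a null scan
  write.table(
    data.frame(rsid = risk_snps$rsid, af = risk_snps$maf,
               an = 2L * 64603L),
    .ws(workspace, "reference_freqs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  set.seed(seed + 17)
  dos <- matrix(rbinom(sc$n_cohort * nrow(risk_snps), 2L,
                       rep(risk_snps$maf, each = sc$n_cohort)),
                nrow = sc$n_cohort)
  # planted NA MAFs (criterion-2 SNPs) get a nominal draw frequency of 0.2
  dos[, is.na(risk_snps$maf)] <- rbinom(
    sc$n_cohort * sum(is.na(risk_snps$maf)), 2L, 0.2)
  cohort_risk <- genotype_matrix(
    dos, individual_ids = sprintf("cff%03d", seq_len(sc$n_cohort)),
    variant_ids = risk_snps$rsid)
  write.table(
    data.frame(individual = rownames(cohort_risk), unclass(cohort_risk),
               check.names = FALSE),
    .ws(workspace, "cohort_risk_dosages.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  # predisposition gene lists: a broad list and a core subset, the core
  # list containing the high-risk screening panel
  broad <- c(sprintf("CPG%03d", 1:48), HIGH_RISK_PANEL)
  core <- c(sprintf("CPG%03d", 1:6), HIGH_RISK_PANEL)
  writeLines(broad, .ws(workspace, "genes_broad.txt"))
  writeLines(core, .ws(workspace, "genes_core.txt"))

  # cohort rare-variant side: annotations + VCF + depth table
  n_rare <- sc$n_rare_variants
  mix <- rep(c("all_pass", "fail_maf", "fail_cadd", "fail_conservation",
               "fail_deleteriousness"), length.out = n_rare)
  ann <- gen_annotated_variants(n_rare, mix, seed = seed + 29,
                                genes = broad)
  lof_idx <- seq(1, n_rare, by = 10)
  ann$consequence[lof_idx] <- sample(LOF_CONSEQUENCES, length(lof_idx),
                                     replace = TRUE)
  write_annotations(ann, .ws(workspace, "annotations.tsv"))

  freqs <- runif(n_rare, 0.005, 0.03)  # cohort draw frequencies for carriage
  cohort <- gen_cohort(sc$n_cohort, freqs, seed = seed + 31, depth = TRUE,
                       mean_depth = sc$mean_depth,
                       low_depth_rate = sc$low_depth_rate,
                       n_low_qual = sc$n_low_qual)
  cohort$variants[, c("chrom", "pos", "ref", "alt")] <-
    ann[, c("chrom", "pos", "ref", "alt")]
  colnames(cohort$genotypes) <- variant_key(ann$chrom, ann$pos, ann$ref,
                                            ann$alt)
  cohort$variants$id <- ann$rsid
  write_cohort_vcf(cohort$genotypes, cohort$variants,
                   .ws(workspace, "cohort.vcf"))
  write.table(
    data.frame(key = colnames(cohort$genotypes), t(cohort$depth),
               check.names = FALSE),
    .ws(workspace, "depth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # reference site counts per (gene-list role x class), ClinVar-labelled
  m <- sc$n_reference_sites_per_class
  classes <- rep(c("non_synonymous", "lof"), each = 2 * m)
  lists <- rep(rep(c("broad", "core"), each = m), 2)
  set.seed(seed + 41)
  genes <- ifelse(lists == "broad", sample(broad, 4 * m, replace = TRUE),
                  sample(core, 4 * m, replace = TRUE))
  site_freq <- runif(4 * m, 1e-4, 2e-3)
  sites <- gen_reference_sites(sc$n_reference_exome, site_freq,
                               seed = seed + 43, genes = genes)
  sites$class <- classes
  sites$gene_list <- lists
  sites$clinvar <- sample(c("pathogenic", "likely_pathogenic", "benign",
                            "uncertain", "absent"), 4 * m, replace = TRUE,
                          prob = c(0.05, 0.05, 0.4, 0.3, 0.2))
  sites$pos <- seq_len(nrow(sites)) * 50L  # unique positions across classes
  write.table(sites, .ws(workspace, "ref_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  report <- data.frame(
    artifact = c("risk_snps", "reference_panel", "reference_freqs",
                 "cohort_risk_dosages", "annotations", "cohort_vcf",
                 "depth", "ref_sites", "genes_broad", "genes_core"),
    rows = c(nrow(risk_snps), sc$n_reference_panel, nrow(risk_snps),
             sc$n_cohort, n_rare, sc$n_cohort, n_rare, nrow(sites),
             length(broad), length(core)))
  path <- .ws(workspace, "simulate_report.tsv")
  write_report(report, path, "simulate", config, config$seed)
  list(report = path)
}

# -- qc -----------------------------------------------------------------

.read_depth <- function(workspace) {
  d <- read.delim(.ws(workspace, "depth.tsv"), check.names = FALSE)
  m <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(m) <- d$key
  m
}

.stage_qc <- function(workspace, config) {
  qc <- config$qc
  vcf <- read_cohort_vcf(.ws(workspace, "cohort.vcf"))
  depth <- .read_depth(workspace)
  filtered <- variant_qc(vcf$genotypes, depth, vcf$variants$qual,
                         min_depth = qc$min_depth, min_qual = qc$min_qual)
  mask <- site_mask(depth, min_depth = qc$site_min_depth,
                    min_fraction = qc$site_min_fraction)
  keep <- colnames(filtered)[colnames(filtered) %in%
                               colnames(depth)[mask]]
  final <- genotype_matrix(unclass(filtered)[, keep, drop = FALSE],
                           individual_ids = rownames(filtered),
                           variant_ids = keep)
  kept_var <- vcf$variants[variant_key(vcf$variants$chrom, vcf$variants$pos,
                                       vcf$variants$ref,
                                       vcf$variants$alt) %in% keep, ]
  write_cohort_vcf(final, kept_var, .ws(workspace, "cohort_qc.vcf"))
  # relatedness is estimated from the common risk-SNP dosages: rare-variant
  # matrices are nearly all homozygous reference, which makes concordance
  # uninformatively high for every pair
  rel <- pairwise_relatedness(.read_cohort_risk(workspace),
                              flag_threshold = qc$relatedness_flag)
  write_report(rel$flagged, .ws(workspace, "relatedness.tsv"), "qc",
               config, config$seed)
  summary <- data.frame(
    metric = c("variants_in", "variants_after_qual", "variants_after_mask",
               "calls_set_missing", "flagged_pairs"),
    value = c(ncol(vcf$genotypes), ncol(filtered), ncol(final),
              sum(is.na(final)) - sum(is.na(vcf$genotypes[, keep])),
              nrow(rel$flagged)))
  path <- .ws(workspace, "qc_report.tsv")
  write_report(summary, path, "qc", config, config$seed)
  list(report = path, relatedness = .ws(workspace, "relatedness.tsv"))
}

# -- select_snps --------------------------------------------------------

.read_reference_panel <- function(workspace) {
  d <- read.delim(.ws(workspace, "reference_panel.tsv"), check.names = FALSE)
  genotype_matrix(as.matrix(d[, -1, drop = FALSE]),
                  individual_ids = d$individual)
}

.stage_select_snps <- function(workspace, config) {
  sel <- config$select_snps
  snps <- read_risk_snps(.ws(workspace, "risk_snps.tsv"))
  panel <- .read_reference_panel(workspace)
  retained <- list(); exclusions <- list()
  for (ct in unique(snps$cancer_type)) {
    res <- filter_risk_snps(snps[snps$cancer_type == ct, ],
                            reference_genotypes = panel,
                            maf_interval = sel$maf_interval,
                            min_or = sel$min_or,
                            r2_threshold = sel$r2_threshold)
    retained[[ct]] <- res$retained
    exclusions[[ct]] <- res$exclusions
  }
  retained <- do.call(rbind, retained)
  exclusions <- do.call(rbind, exclusions)
  write_risk_snps(retained, .ws(workspace, "risk_snps_retained.tsv"))
  path <- .ws(workspace, "snp_exclusions.tsv")
  write_report(exclusions, path, "select_snps", config, config$seed)
  list(retained = .ws(workspace, "risk_snps_retained.tsv"),
       exclusions = path)
}

# -- allele_scan --------------------------------------------------------

.read_cohort_risk <- function(workspace) {
  d <- read.delim(.ws(workspace, "cohort_risk_dosages.tsv"),
                  check.names = FALSE)
  genotype_matrix(as.matrix(d[, -1, drop = FALSE]),
                  individual_ids = d$individual)
}

.stage_allele_scan <- function(workspace, config) {
  snps <- read_risk_snps(.ws(workspace, "risk_snps_retained.tsv"))
  cohort <- .read_cohort_risk(workspace)
  freqs <- read.delim(.ws(workspace, "reference_freqs.tsv"))
  out <- list()
  for (ct in unique(snps$cancer_type)) {
    scan <- allele_scan(cohort, freqs, snps[snps$cancer_type == ct, ],
                        alpha = config$allele_scan$alpha)
    bonf <- attr(scan, "bonferroni")
    scan$cancer_type <- ct
    scan$bonferroni_level <- bonf$display
    out[[ct]] <- scan
  }
  out <- do.call(rbind, out)
  path <- .ws(workspace, "allele_scan.tsv")
  write_report(out, path, "allele_scan", config, config$seed)
  list(report = path)
}

# -- burden -------------------------------------------------------------

.stage_burden <- function(workspace, config) {
  snps <- read_risk_snps(.ws(workspace, "risk_snps_retained.tsv"))
  cohort <- .read_cohort_risk(workspace)
  panel <- .read_reference_panel(workspace)
  out <- list()
  for (ct in unique(snps$cancer_type)) {
    sub <- snps[snps$cancer_type == ct, ]
    ref_tot <- count_risk_alleles(panel, sub,
                                  missing = config$burden$missing)
    coh_tot <- count_risk_alleles(cohort, sub,
                                  missing = config$burden$missing)
    tab <- quartile_table(ref_tot, coh_tot)
    tab$cancer_type <- ct
    tab$trend_p <- attr(tab, "trend_p")
    out[[ct]] <- tab
  }
  out <- do.call(rbind, out)
  path <- .ws(workspace, "burden.tsv")
  write_report(out, path, "burden", config, config$seed)
  list(report = path)
}

# -- prioritize ---------------------------------------------------------

.stage_prioritize <- function(workspace, config) {
  pr <- config$prioritize
  ann <- read_annotations(.ws(workspace, "annotations.tsv"))
  lists <- list(broad = read_gene_list(.ws(workspace, "genes_broad.txt")),
                core = read_gene_list(.ws(workspace, "genes_core.txt")))
  audits <- list(); survivors <- list()
  for (ln in names(lists)) {
    for (cl in c("non_synonymous", "lof")) {
      res <- fcvpp_cascade(ann, lists[[ln]], cl,
                           maf_threshold = pr$maf_threshold,
                           cadd_threshold = pr$cadd_threshold,
                           strict_missing = pr$strict_missing)
      if (nrow(res$audit) > 0) {
        res$audit$gene_list <- ln
        res$audit$class <- cl
        audits[[paste(ln, cl)]] <- res$audit
      }
      if (nrow(res$survivors) > 0) {
        surv <- res$survivors
        surv$gene_list <- ln
        surv$class <- cl
        survivors[[paste(ln, cl)]] <- surv[, c("chrom", "pos", "ref",
                                               "alt", "gene", "gene_list",
                                               "class")]
      }
    }
  }
  audit <- do.call(rbind, audits)
  surv <- do.call(rbind, survivors)
  path <- .ws(workspace, "prioritization_audit.tsv")
  write_report(audit, path, "prioritize", config, config$seed)
  write_report(surv, .ws(workspace, "prioritization_survivors.tsv"),
               "prioritize", config, config$seed)
  list(audit = path,
       survivors = .ws(workspace, "prioritization_survivors.tsv"))
}

# -- carrier ------------------------------------------------------------

.stage_carrier <- function(workspace, config) {
  surv <- read_report(.ws(workspace, "prioritization_survivors.tsv"))
  vcf <- read_cohort_vcf(.ws(workspace, "cohort_qc.vcf"))
  sites <- read.delim(.ws(workspace, "ref_sites.tsv"))
  scenarios <- list()
  for (ln in c("broad", "core")) {
    for (cl in c("non_synonymous", "lof")) {
      keys <- variant_key(surv$chrom, surv$pos, surv$ref, surv$alt)[
        surv$gene_list == ln & surv$class == cl]
      coh <- cohort_carrier_probability(vcf$genotypes, keys)
      ref <- sites[sites$gene_list == ln & sites$class == cl, ]
      scenarios[[paste0(ln, "_", cl)]] <- list(
        cohort_indicators = coh$indicators,
        n_cohort_variants = sum(keys %in% colnames(vcf$genotypes)),
        reference_q = carrier_freq(ref$ac, ref$hom, ref$an))
    }
  }
  report_df <- carrier_report(scenarios, n_boot = config$carrier$n_boot,
                              seed = .stage_seed(config, "carrier"))
  path <- .ws(workspace, "carrier.tsv")
  write_report(report_df, path, "carrier", config, config$seed)
  list(report = path)
}

# -- highrisk -----------------------------------------------------------

.stage_highrisk <- function(workspace, config) {
  hr <- config$highrisk
  ann <- read_annotations(.ws(workspace, "annotations.tsv"))
  # panel genes can legitimately lack variant records in a small cohort;
  # they still get "Not found" rows, so the warning is noise here
  screen <- suppressWarnings(
    screen_high_risk(ann, HIGH_RISK_PANEL,
                     maf_threshold = hr$maf_threshold,
                     freq_source = hr$freq_source))
  sites <- read.delim(.ws(workspace, "ref_sites.tsv"))
  refp <- reference_pathogenic_probability(
    sites, genes = intersect(HIGH_RISK_PANEL, sites$gene))
  path <- .ws(workspace, "highrisk.tsv")
  write_report(screen, path, "highrisk", config, config$seed)
  write_report(refp, .ws(workspace, "highrisk_reference.tsv"), "highrisk",
               config, config$seed)
  list(screen = path,
       reference = .ws(workspace, "highrisk_reference.tsv"))
}
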