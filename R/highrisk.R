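# High-risk gene screen: rare missense / loss-of-function variants in a
# fixed predisposition panel (BRCA1/2, the colorectal mismatch-repair and
# polyposis genes, HOXB13), annotated with CADD, conservation and
# deleteriousness votes and ClinVar significance, plus the per-gene
# probability that a reference individual carries a pathogenic variant.

# Static caveats carried into reports; annotation only, never logic.
.panel_notes <- c(
  MUTYH = "recessive predisposition gene; single-allele carriers need a second hit",
  PMS2 = "high-risk status under discussion",
  HOXB13 = "high-risk status under discussion"
)

#' Screen a high-risk gene panel for rare missense/LoF variants
#'
#' Retains missense and loss-of-function variants in the panel genes with
#' allele frequency strictly below `maf_threshold` in the designated
#' frequency source, and reports each with its reference prevalence, CADD
#' score, conservation and deleteriousness votes (in "k/n" form) and
#' ClinVar significance.  Panel genes with no qualifying variant appear
#' as a single `"Not found"` row, and a variant without an rsID is
#' reported as `"No dbSNP"`.  The frequency source is a parameter because
#' published screens differ on which population the cutoff addresses.
#'
#' @param variants annotated-variant data.frame (cohort side)
#' @param panel character vector of panel gene symbols
#' @param maf_threshold frequency cutoff (strict `<`)
#' @param freq_source which MAF source the cutoff applies to, one of
#'   [MAF_SOURCES]
#' @param prevalence_source MAF source reported as the reference
#'   prevalence column
#' @return data.frame with one row per retained variant plus one
#'   `"Not found"` row per hit-less panel gene
#' @export
screen_high_risk <- function(variants, panel = HIGH_RISK_PANEL,
                             maf_threshold = 0.001,
                             freq_source = "thousand_genomes",
                             prevalence_source = "exac_nfe_nontcga") {
  freq_source <- match.arg(freq_source, MAF_SOURCES)
  prevalence_source <- match.arg(prevalence_source, MAF_SOURCES)
  unknown <- setdiff(panel, variants$gene)
  class_ok <- variants$consequence %in% c("missense", LOF_CONSEQUENCES)
  maf <- variants[[paste0("maf_", freq_source)]]
  rare <- is.na(maf) | maf < maf_threshold
  hits <- variants[class_ok & rare & variants$gene %in% panel, ,
                   drop = FALSE]
  cons <- conservation_vote(hits)
  dele <- deleteriousness_vote(hits)
  rows <- data.frame(
    gene = hits$gene,
    snp_id = ifelse(is.na(hits$rsid) | hits$rsid == "", "No dbSNP",
                    hits$rsid),
    chrom = hits$chrom, pos = hits$pos,
    ref_alt = paste0(hits$ref, "/", hits$alt),
    prevalence_reference = hits[[paste0("maf_", prevalence_source)]],
    cadd = hits$cadd_phred,
    conservation_votes = cons$votes,
    prediction_votes = paste0(dele$votes, "/", dele$available),
    clinvar = hits$clinvar,
    clinvar_raw = ifelse(is.na(hits$clinvar_raw), "-", hits$clinvar_raw),
    note = ifelse(hits$gene %in% names(.panel_notes),
                  .panel_notes[hits$gene], ""))
  empty <- setdiff(panel, rows$gene)
  if (length(empty) > 0) {
    rows <- rbind(rows, data.frame(
      gene = empty, snp_id = "Not found", chrom = NA, pos = NA,
      ref_alt = NA, prevalence_reference = NA, cadd = NA,
      conservation_votes = NA, prediction_votes = NA, clinvar = NA,
      clinvar_raw = NA,
      note = ifelse(empty %in% names(.panel_notes),
                    .panel_notes[empty], "")))
  }
  rows <- rows[order(match(rows$gene, panel), rows$pos), , drop = FALSE]
  rownames(rows) <- NULL
  if (length(unknown) > 0) {
    warning("panel genes with no variant records at all: ",
            paste(unknown, collapse = ", "))
  }
  rows
}

#' Reference probability of carrying a ClinVar-pathogenic variant, per gene
#'
#' Restricts the reference site-count table (joined to ClinVar labels) to
#' pathogenic / likely-pathogenic variants and aggregates their carrier
#' frequencies with [carrier_probability()], per gene.  A gene with no
#' pathogenic variant has probability 0.
#'
#' @param sites site-count data.frame with columns gene, ac, hom, an and
#'   clinvar (normalized, see [normalize_clinvar()])
#' @param genes genes to report; defaults to those present in `sites`
#' @return data.frame with gene, n_variants, n_pathogenic,
#'   p_pathogenic_carrier
#' @export
reference_pathogenic_probability <- function(sites,
                                             genes = unique(sites$gene)) {
  rows <- lapply(genes, function(g) {
    sub <- sites[sites$gene == g, , drop = FALSE]
    path <- sub[sub$clinvar %in% c("pathogenic", "likely_pathogenic"), ,
                drop = FALSE]
    p <- if (nrow(path) == 0) 0 else
      carrier_probability(carrier_freq(path$ac, path$hom, path$an))
    data.frame(gene = g, n_variants = nrow(sub),
               n_pathogenic = nrow(path), p_pathogenic_carrier = p)
  })
  do.call(rbind, rows)
}
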