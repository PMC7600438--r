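# Domain types: plain data.frames with constructor/validator pairs, in the
# style of the lighter Bioconductor infrastructure packages.  All joins are
# on the (chrom, pos, ref, alt) key, 1-based fully-closed VCF coordinates.

#' Build the canonical variant key
#'
#' @param chrom,pos,ref,alt vectors describing bi-allelic variants
#' @return character vector `"chrom:pos:ref:alt"`
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Construct a genotype dosage matrix
#'
#' Rows are individuals, columns variants; entries count alternate (or risk)
#' alleles, so valid values are 0, 1, 2 or `NA` for a missing call.
#'
#' @param dosages numeric/integer matrix
#' @param individual_ids,variant_ids optional dimension names
#' @return integer matrix of class `genotype_matrix`
#' @export
genotype_matrix <- function(dosages, individual_ids = rownames(dosages),
                            variant_ids = colnames(dosages)) {
  m <- as.matrix(dosages)
  storage.mode(m) <- "integer"
  bad <- !(m %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found: ",
         paste(unique(m[bad]), collapse = ", "))
  }
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(m)))
  if (is.null(variant_ids)) variant_ids <- paste0("var", seq_len(ncol(m)))
  stopifnot(length(individual_ids) == nrow(m),
            length(variant_ids) == ncol(m))
  dimnames(m) <- list(individual_ids, variant_ids)
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' Validate a reference site-count table
#'
#' A site-count row carries the alternate allele count (AC), the number of
#' homozygous-alternate individuals (Hom) and the total allele number (AN)
#' for one variant, as published in ExAC/gnomAD-style exports.  The
#' invariants are: AN positive and even, 2*Hom <= AC <= AN.  The number of
#' carriers of at least one alternate allele is AC - Hom.
#'
#' @param x data.frame with columns chrom, pos, ref, alt, ac, hom, an
#' @return list with elements `accepted` (valid rows), `rejected` (invalid
#'   rows with a `reason` column); `nrow(accepted) + nrow(rejected) ==
#'   nrow(x)` always holds.
#' @export
validate_site_counts <- function(x) {
  required <- c("chrom", "pos", "ref", "alt", "ac", "hom", "an")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("site-count table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  reason <- character(nrow(x))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[cond & reason == ""] <<- msg
  }
  bad(x$an <= 0, "an must be positive")
  bad(x$an %% 2 != 0, "an must be even")
  bad(x$ac < 0 | x$hom < 0, "counts must be non-negative")
  bad(x$ac > x$an, "ac exceeds an")
  bad(2 * x$hom > x$ac, "2*hom exceeds ac")
  keep <- reason == ""
  rejected <- x[!keep, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!keep]
  list(accepted = x[keep, , drop = FALSE], rejected = rejected)
}

#' Validate an annotated-variant table
#'
#' Checks the closed consequence and ClinVar vocabularies, MAF ranges and
#' the presence of all ten predictor columns (see [PREDICTOR_TOOLS]).
#'
#' @param x data.frame as returned by [read_annotations()] or
#'   [gen_annotated_variants()]
#' @return `x` invisibly; errors describe the first violation found
#' @export
validate_annotated_variants <- function(x) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "gene", "consequence",
                  "clinvar") %in% names(x)))
  if (any(x$pos < 1)) stop("pos must be >= 1")
  if (!all(x$consequence %in% CONSEQUENCE_LEVELS)) {
    stop("unknown consequence: ",
         paste(setdiff(unique(x$consequence), CONSEQUENCE_LEVELS), collapse = ", "))
  }
  if (!all(x$clinvar %in% CLINVAR_LEVELS)) {
    stop("unknown clinvar category: ",
         paste(setdiff(unique(x$clinvar), CLINVAR_LEVELS), collapse = ", "))
  }
  maf_cols <- paste0("maf_", MAF_SOURCES)
  for (col in intersect(maf_cols, names(x))) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop(col, " outside [0,1]")
  }
  pred_cols <- paste0("pred_", PREDICTOR_TOOLS)
  missing_pred <- setdiff(pred_cols, names(x))
  if (length(missing_pred) > 0) {
    stop("missing predictor columns: ", paste(missing_pred, collapse = ", "))
  }
  for (col in pred_cols) {
    if (!all(x[[col]] %in% c("deleterious", "tolerated", "missing"))) {
      stop("predictor column ", col, " has values outside ",
           "{deleterious, tolerated, missing}")
    }
  }
  invisible(x)
}

#' Validate a GWAS risk-SNP table
#'
#' @param x data.frame with columns rsid, cancer_type, chrom, pos,
#'   risk_allele, maf, or_published, subtype_specific, in_thousand_genomes.
#'   Unspecified risk alleles/MAFs/ORs are `NA`.
#' @return `x` invisibly
#' @export
validate_risk_snps <- function(x) {
  required <- c("rsid", "cancer_type", "chrom", "pos", "risk_allele", "maf",
                "or_published", "subtype_specific", "in_thousand_genomes")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("risk-SNP table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$rsid)) {
    stop("duplicate rsIDs: ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "))
  }
  if (!all(x$cancer_type %in% c("BC", "CRC", "PC"))) {
    stop("cancer_type must be one of BC, CRC, PC")
  }
  ok_maf <- is.na(x$maf) | (x$maf >= 0 & x$maf <= 1)
  if (!all(ok_maf)) stop("maf outside [0,1]")
  invisible(x)
}

#' Collapse a raw ClinVar significance string to one category
#'
#' Compound values such as `"Likely benign/US"` or
#' `"Likely Pathogenic/Pathogenic"` collapse to the most severe listed
#' category (severity order given by [CLINVAR_LEVELS]); the raw string is
#' kept by the readers for reporting.
#'
#' @param x character vector of raw ClinVar strings; `NA`/`""`/`"."`/`"-"`
#'   mean absent
#' @return character vector over [CLINVAR_LEVELS]
#' @export
normalize_clinvar <- function(x) {
  map_one <- function(s) {
    if (is.na(s) || s %in% c("", ".", "-")) return("absent")
    parts <- tolower(trimws(strsplit(s, "[/,;|]")[[1]]))
    cats <- vapply(parts, function(p) {
      if (p %in% c("us", "uncertain significance", "uncertain",
                   "vus")) return("uncertain")
      if (p %in% c("likely pathogenic", "likely_pathogenic")) return("likely_pathogenic")
      if (p %in% c("pathogenic")) return("pathogenic")
      if (p %in% c("likely benign", "likely_benign")) return("likely_benign")
      if (p %in% c("benign")) return("benign")
      if (p %in% c("not provided", "not_provided")) return("not_provided")
      if (p == "absent") return("absent")
      stop("unrecognized ClinVar significance: '", p, "'")
    }, character(1))
    CLINVAR_LEVELS[min(match(cats, CLINVAR_LEVELS))]
  }
  vapply(x, map_one, character(1), USE.NAMES = FALSE)
}
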