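# Readers and writers for the formats the pipeline touches: VCF 4.x for
# cohort genotypes (parsed with vcfR), TSV for annotations / site counts /
# risk-SNP lists, one-symbol-per-line gene lists, and TSV reports with a
# provenance header.

# Per-tool synonym maps for deleteriousness predictor codes (dbNSFP-style
# one-letter calls).  Codes meaning "damaging" map to deleterious; "U"
# (LRT unknown) maps to missing.
.predictor_synonyms <- local({
  generic <- c(D = "deleterious", T = "tolerated",
               deleterious = "deleterious", tolerated = "tolerated")
  list(
    SIFT = generic,
    PolyPhen2_HDIV = c(D = "deleterious", P = "deleterious", B = "tolerated",
                       generic),
    PolyPhen2_HVAR = c(D = "deleterious", P = "deleterious", B = "tolerated",
                       generic),
    LRT = c(D = "deleterious", N = "tolerated", U = "missing", generic),
    MutationTaster = c(A = "deleterious", D = "deleterious", N = "tolerated",
                       P = "tolerated",
                       deleterious = "deleterious", tolerated = "tolerated"),
    MutationAssessor = c(H = "deleterious", M = "deleterious",
                         L = "tolerated", N = "tolerated", generic),
    FATHMM = generic,
    MetaSVM = generic,
    MetaLR = generic,
    PROVEAN = c(D = "deleterious", N = "tolerated", generic)
  )
})

#' Normalize one predictor column to the three-way call vocabulary
#'
#' @param codes character vector of raw tool codes
#' @param tool one of [PREDICTOR_TOOLS]
#' @return character vector over `{deleterious, tolerated, missing}`
#' @export
normalize_predictor <- function(codes, tool) {
  tool <- match.arg(tool, PREDICTOR_TOOLS)
  map <- .predictor_synonyms[[tool]]
  out <- character(length(codes))
  blank <- is.na(codes) | codes %in% c("", ".", "-", "missing")
  out[blank] <- "missing"
  known <- !blank & codes %in% names(map)
  out[known] <- unname(map[codes[known]])
  bad <- !blank & !known
  if (any(bad)) {
    stop("unknown ", tool, " predictor code: '",
         codes[which(bad)[1]], "'")
  }
  out
}

#' Read a cohort VCF into a dosage matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts GT fields to
#' alternate-allele dosages.  Multi-allelic records are split into one
#' bi-allelic entry per alternate allele; a genotype's dosage for an entry
#' is the number of alleles matching that alternate.  Missing genotypes
#' (`./.`) become `NA`.
#'
#' @param path VCF file (plain text or bgzipped)
#' @return list with `genotypes` (a [genotype_matrix()], individuals x
#'   variants) and `variants` (data.frame chrom/pos/ref/alt/id/qual)
#' @export
read_cohort_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  samples <- colnames(gt)
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt_field <- fix[, "ALT"]
  id <- fix[, "ID"]; qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  rows <- list(); dose_cols <- list()
  for (i in seq_along(chrom)) {
    alts <- strsplit(alt_field[i], ",", fixed = TRUE)[[1]]
    gt_row <- gt[i, ]
    gt_row[is.na(gt_row)] <- "."
    alleles <- strsplit(gt_row, "[/|]")
    for (j in seq_along(alts)) {
      dos <- vapply(alleles, function(a) {
        if (length(a) == 0 || any(a %in% c(".", ""))) return(NA_integer_)
        ai <- suppressWarnings(as.integer(a))
        if (any(is.na(ai))) {
          stop("malformed GT '", paste(a, collapse = "/"),
               "' at ", chrom[i], ":", pos[i])
        }
        sum(ai == j)
      }, integer(1))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[j],
        id = id[i], qual = qual[i], stringsAsFactors = FALSE)
      dose_cols[[length(dose_cols) + 1L]] <- dos
    }
  }
  variants <- do.call(rbind, rows)
  dosages <- do.call(cbind, dose_cols)
  gm <- genotype_matrix(dosages, individual_ids = samples,
                        variant_ids = variant_key(variants$chrom, variants$pos,
                                                  variants$ref, variants$alt))
  list(genotypes = gm, variants = variants)
}

#' Write a dosage matrix as a minimal VCF 4.2
#'
#' Inverse of [read_cohort_vcf()] for bi-allelic sites: emits one record
#' per variant with a GT-only FORMAT, `0/1` for dosage 1, `./.` for `NA`.
#'
#' @param genotypes a [genotype_matrix()]
#' @param variants data.frame chrom/pos/ref/alt (and optional id, qual)
#' @param path output file
#' @return `path` invisibly
#' @export
write_cohort_vcf <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  id <- if ("id" %in% names(variants)) variants$id else rep(".", nrow(variants))
  qual <- if ("qual" %in% names(variants)) variants$qual else rep(".", nrow(variants))
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  body <- vapply(seq_len(nrow(variants)), function(i) {
    g <- genotypes[, i]
    gts <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(variants$chrom[i], variants$pos[i], id[i], variants$ref[i],
            variants$alt[i], qual[i], "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ExAC-style site-count table
#'
#' Expects a TSV with columns chrom, pos, ref, alt, ac, hom, an (case
#' insensitive; AC/Hom/AN accepted).  Rows violating the site-count
#' invariants are split off into a rejection report rather than silently
#' dropped.
#'
#' @param path TSV file
#' @param strict error (rather than warn) when any row is rejected
#' @return data.frame of accepted rows with the rejection report (possibly
#'   empty) in `attr(, "rejected")`
#' @export
read_site_counts <- function(path, strict = FALSE) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(x) <- sub("^AC$", "ac", sub("^Hom$", "hom", sub("^AN$", "an", names(x))))
  names(x) <- tolower(names(x))
  x$chrom <- as.character(x$chrom)
  split <- validate_site_counts(x)
  if (nrow(split$rejected) > 0) {
    msg <- paste0(nrow(split$rejected), " site-count rows rejected (first: ",
                  split$rejected$reason[1], ")")
    if (strict) stop(msg) else warning(msg)
  }
  out <- split$accepted
  attr(out, "rejected") <- split$rejected
  out
}

#' @rdname read_site_counts
#' @param x site-count data.frame
#' @export
write_site_counts <- function(x, path) {
  write.table(x[, c("chrom", "pos", "ref", "alt", "ac", "hom", "an")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotated-variant table
#'
#' Consumes a TSV with the documented column dictionary: the variant key
#' (chrom, pos, ref, alt), gene, consequence, rsid, per-source MAFs
#' (`maf_thousand_genomes`, `maf_exac_nfe_nontcga`, `maf_local`),
#' `cadd_phred`, conservation scores (gerp, phastcons, phylop), one column
#' per deleteriousness predictor (raw tool codes; see
#' [normalize_predictor()]), optional intolerance ranks (`intol_esp`,
#' `intol_exac`, `intol_local`, `mis_z`) and a raw `clinvar` string.
#' Optional columns may be absent entirely.  Predictor codes are
#' normalized to `{deleterious, tolerated, missing}` and ClinVar strings
#' are collapsed via [normalize_clinvar()] (the raw string is kept in
#' `clinvar_raw`).
#'
#' @param path TSV file
#' @return validated annotated-variant data.frame
#' @export
read_annotations <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("NA", "", "."))
  x$chrom <- as.character(x$chrom)
  for (tool in PREDICTOR_TOOLS) {
    raw_col <- if (tool %in% names(x)) x[[tool]] else rep(NA_character_, nrow(x))
    x[[paste0("pred_", tool)]] <- normalize_predictor(as.character(raw_col), tool)
    x[[tool]] <- NULL
  }
  raw_clinvar <- if ("clinvar" %in% names(x)) as.character(x[["clinvar"]]) else
    rep(NA_character_, nrow(x))
  x$clinvar_raw <- raw_clinvar
  x$clinvar <- normalize_clinvar(raw_clinvar)
  optional_num <- c(paste0("maf_", MAF_SOURCES), "cadd_phred", "gerp",
                    "phastcons", "phylop", "intol_esp", "intol_exac",
                    "intol_local", "mis_z")
  for (col in optional_num) {
    x[[col]] <- if (col %in% names(x)) as.numeric(x[[col]]) else NA_real_
  }
  if (!"rsid" %in% names(x)) x$rsid <- NA_character_
  validate_annotated_variants(x)
  x
}

#' @rdname read_annotations
#' @param x annotated-variant data.frame
#' @export
write_annotations <- function(x, path) {
  out <- x
  for (tool in PREDICTOR_TOOLS) {
    out[[tool]] <- out[[paste0("pred_", tool)]]
    out[[paste0("pred_", tool)]] <- NULL
  }
  out$clinvar <- ifelse(is.na(out$clinvar_raw), out$clinvar, out$clinvar_raw)
  out$clinvar_raw <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a GWAS risk-SNP list
#'
#' @param path TSV with columns rsid, cancer_type, chrom, pos, risk_allele,
#'   maf, or_published, subtype_specific, in_thousand_genomes
#' @return validated risk-SNP data.frame
#' @export
read_risk_snps <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", "", "."))
  x$chrom <- as.character(x$chrom)
  x$risk_allele <- as.character(x$risk_allele)
  x$subtype_specific <- as.logical(x$subtype_specific)
  x$in_thousand_genomes <- as.logical(x$in_thousand_genomes)
  validate_risk_snps(x)
  x
}

#' @rdname read_risk_snps
#' @param x risk-SNP data.frame
#' @export
write_risk_snps <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and `#` comments are ignored; duplicates are dropped.
#' @param path text file
#' @return character vector of gene symbols
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[x != "" & !startsWith(x, "#")]
  unique(x)
}

#' Write a TSV report with a provenance header
#'
#' Every pipeline report starts with comment lines echoing the stage name,
#' a hash of the configuration and the seed, so runs are auditable and
#' byte-comparable.
#'
#' @param x data.frame
#' @param path output file
#' @param stage stage name for the header
#' @param config list echoed (hashed) in the header
#' @param seed integer seed echoed in the header
#' @return `path` invisibly
#' @export
write_report <- function(x, path, stage = "report", config = list(),
                         seed = NA) {
  hash <- config_hash(config)
  header <- c(sprintf("# cffpipe stage=%s", stage),
              sprintf("# config_hash=%s seed=%s", hash, seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = ""))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Hash a configuration list
#'
#' MD5 of the canonical (sorted-key) JSON serialization.
#' @param config list
#' @return character scalar
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}
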