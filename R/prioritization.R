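# The variant-prioritization cascade: a conjunctive filter over rarity
# (MAF), deleteriousness (CADD), evolutionary conservation (three-tool
# vote) and missense-predictor consensus (ten-tool strict majority), with
# an intolerance screen that annotates but does not block by default.
# Every variant receives a per-stage audit, so the surviving set is the
# intersection of the per-stage pass sets regardless of stage order.

#' Rarity filter over all available frequency sources
#'
#' A variant passes when its allele frequency is strictly below
#' `threshold` in every available source (1000 Genomes, non-Finnish
#' European non-TCGA ExAC, local cohort).  Sources without a value are
#' treated as passing: frequency unknown is read as rare.  A variant with
#' no source at all is not evaluated.
#'
#' @param variants annotated-variant data.frame
#' @param threshold MAF cutoff (strict `<`)
#' @return character vector per variant: `"pass"`, `"fail"` or
#'   `"not_evaluated"`
#' @export
maf_filter <- function(variants, threshold = 0.001) {
  maf <- as.matrix(variants[, paste0("maf_", MAF_SOURCES), drop = FALSE])
  n_avail <- rowSums(!is.na(maf))
  any_common <- rowSums(!is.na(maf) & maf >= threshold) > 0
  ifelse(n_avail == 0, "not_evaluated",
         ifelse(any_common, "fail", "pass"))
}

#' CADD deleteriousness filter
#'
#' Passes variants with scaled (PHRED-like) CADD strictly greater than
#' `threshold`; the default 10 keeps roughly the top decile of possible
#' substitutions.  A missing score is not evaluated unless
#' `strict_missing` is set, in which case it fails.
#'
#' @param variants annotated-variant data.frame
#' @param threshold scaled CADD cutoff (strict `>`)
#' @param strict_missing fail variants without a CADD score
#' @return per-variant `"pass"` / `"fail"` / `"not_evaluated"`
#' @export
cadd_filter <- function(variants, threshold = 10, strict_missing = FALSE) {
  sc <- variants$cadd_phred
  miss <- is.na(sc)
  out <- ifelse(miss, if (strict_missing) "fail" else "not_evaluated",
                ifelse(sc > threshold, "pass", "fail"))
  out
}

#' Conservation vote over GERP, PhastCons and PhyloP
#'
#' A tool votes "conserved" when GERP > 2.0, PhastCons > 0.3 or
#' PhyloP >= 3.0 (PhyloP is the one inclusive threshold).  The variant
#' passes with at least 2 votes among the available tools.
#'
#' @param variants annotated-variant data.frame
#' @param min_votes votes required to pass
#' @return data.frame with `votes`, `available` and `status`
#' @export
conservation_vote <- function(variants, min_votes = 2) {
  v_gerp <- !is.na(variants$gerp) & variants$gerp > 2.0
  v_phast <- !is.na(variants$phastcons) & variants$phastcons > 0.3
  v_phylop <- !is.na(variants$phylop) & variants$phylop >= 3.0
  votes <- v_gerp + v_phast + v_phylop
  available <- (!is.na(variants$gerp)) + (!is.na(variants$phastcons)) +
    (!is.na(variants$phylop))
  status <- ifelse(available == 0, "not_evaluated",
                   ifelse(votes >= min_votes, "pass", "fail"))
  data.frame(votes = votes, available = available, status = status)
}

#' Deleteriousness vote over the ten missense predictors
#'
#' Counts `deleterious` calls among the ten tools ([PREDICTOR_TOOLS]); a
#' variant passes when strictly more than half of the tools with a call
#' say deleterious (with all ten available this is the >= 6/10 rule).  No
#' calls at all means the stage is not evaluated.
#'
#' @param variants annotated-variant data.frame
#' @return data.frame with `votes` (deleterious calls), `available`
#'   (non-missing calls) and `status`
#' @export
deleteriousness_vote <- function(variants) {
  calls <- as.matrix(variants[, paste0("pred_", PREDICTOR_TOOLS),
                              drop = FALSE])
  votes <- rowSums(calls == "deleterious")
  available <- rowSums(calls != "missing")
  status <- ifelse(available == 0, "not_evaluated",
                   ifelse(votes > available / 2, "pass", "fail"))
  data.frame(votes = votes, available = available, status = status)
}

#' Intolerance screen (annotating, non-blocking by default)
#'
#' Attaches the available gene-intolerance ranks (three sources) and the
#' missense Z-score to the audit.  Only when explicit thresholds are
#' supplied does it act as a hard filter: a variant fails if any supplied
#' threshold is violated; without thresholds every variant passes
#' unchanged.
#'
#' @param variants annotated-variant data.frame
#' @param thresholds optional named list with any of `intol_esp`,
#'   `intol_exac`, `intol_local` (maximum rank, inclusive) and `mis_z`
#'   (minimum Z, inclusive)
#' @return data.frame with the four score columns and `status`
#' @export
intolerance_screen <- function(variants, thresholds = NULL) {
  out <- variants[, c("intol_esp", "intol_exac", "intol_local", "mis_z")]
  if (is.null(thresholds) || length(thresholds) == 0) {
    out$status <- rep("pass", nrow(variants))
    return(out)
  }
  fail <- rep(FALSE, nrow(variants))
  for (nm in intersect(c("intol_esp", "intol_exac", "intol_local"),
                       names(thresholds))) {
    fail <- fail | (!is.na(out[[nm]]) & out[[nm]] > thresholds[[nm]])
  }
  if ("mis_z" %in% names(thresholds)) {
    fail <- fail | (!is.na(out$mis_z) & out$mis_z < thresholds$mis_z)
  }
  out$status <- ifelse(fail, "fail", "pass")
  out
}

#' The full prioritization cascade
#'
#' Restricts to variants of the requested consequence class lying in the
#' supplied predisposition-gene list, then applies the rarity, CADD,
#' conservation and deleteriousness stages conjunctively.  The
#' conservation and deleteriousness votes apply to coding non-synonymous
#' (missense) variants only; loss-of-function variants (stop gain/loss,
#' splice site, frameshift indel) are filtered on MAF and CADD alone,
#' since missense predictors do not score them.  `not_evaluated` stages
#' pass through by default (`strict_missing` fails a missing CADD).
#'
#' @param variants annotated-variant data.frame
#' @param gene_list character vector of gene symbols (non-empty)
#' @param consequence_class `"non_synonymous"` (missense) or `"lof"`
#' @param maf_threshold,cadd_threshold stage cutoffs
#' @param intolerance_thresholds passed to [intolerance_screen()]
#' @param strict_missing passed to [cadd_filter()]
#' @return list with `audit` (one row per in-scope variant with per-stage
#'   status, vote strings and final verdict) and `survivors` (the passing
#'   subset of `variants`)
#' @export
fcvpp_cascade <- function(variants, gene_list,
                          consequence_class = c("non_synonymous", "lof"),
                          maf_threshold = 0.001, cadd_threshold = 10,
                          intolerance_thresholds = NULL,
                          strict_missing = FALSE) {
  consequence_class <- match.arg(consequence_class)
  if (length(gene_list) == 0) stop("empty gene list")
  in_class <- if (consequence_class == "non_synonymous") {
    variants$consequence == "missense"
  } else {
    variants$consequence %in% LOF_CONSEQUENCES
  }
  scope <- variants[in_class & variants$gene %in% gene_list, , drop = FALSE]
  if (nrow(scope) == 0) {
    return(list(audit = data.frame(), survivors = scope))
  }
  s_maf <- maf_filter(scope, maf_threshold)
  s_cadd <- cadd_filter(scope, cadd_threshold, strict_missing)
  cons <- conservation_vote(scope)
  dele <- deleteriousness_vote(scope)
  intol <- intolerance_screen(scope, intolerance_thresholds)
  if (consequence_class == "lof") {
    # missense predictors and conservation votes are not applicable to LoF
    cons$status <- rep("not_evaluated", nrow(scope))
    dele$status <- rep("not_evaluated", nrow(scope))
  }
  hard <- cbind(maf = s_maf, cadd = s_cadd, conservation = cons$status,
                deleteriousness = dele$status, intolerance = intol$status)
  final <- apply(hard, 1, function(r) all(r != "fail"))
  audit <- data.frame(
    key = variant_key(scope$chrom, scope$pos, scope$ref, scope$alt),
    gene = scope$gene,
    consequence = scope$consequence,
    maf = s_maf,
    cadd = s_cadd,
    conservation = cons$status,
    conservation_votes = paste0(cons$votes, "/", cons$available),
    deleteriousness = dele$status,
    deleteriousness_votes = paste0(dele$votes, "/", dele$available),
    intolerance = intol$status,
    final = ifelse(final, "pass", "fail"))
  list(audit = audit, survivors = scope[final, , drop = FALSE])
}
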