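test_that("VCF genotypes parse to dosages, with multi-allelic splitting", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(toy_vcf_lines(), path)
  res <- read_cohort_vcf(path)
  # first site: 0/1 -> 1, 1/1 -> 2, ./. -> NA
  expect_equal(unname(res$genotypes[, "1:101:A:G"]), c(1L, 2L, NA))
  # multi-allelic record split into two bi-allelic entries
  expect_true(all(c("2:202:C:T", "2:202:C:G") %in% colnames(res$genotypes)))
  expect_equal(unname(res$genotypes[, "2:202:C:T"]), c(0L, 1L, 0L))
  expect_equal(unname(res$genotypes[, "2:202:C:G"]), c(1L, 1L, 0L))
  expect_equal(nrow(res$variants), 3L)
  expect_error(read_cohort_vcf(withr::local_tempfile()), "no such VCF")
})

test_that("cohort genotypes round-trip through VCF write/read identically", {
  sim <- gen_cohort(3, c(0.5, 0.3), seed = 7)
  sim$genotypes[2, 1] <- NA  # exercise missing-call encoding
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim$genotypes, sim$variants, path)
  back <- read_cohort_vcf(path)
  expect_identical(unclass(back$genotypes)[, colnames(sim$genotypes)],
                   unclass(sim$genotypes))
  expect_equal(back$variants$qual, sim$variants$qual)
})

test_that("site-count validation is total and enforces the invariants", {
  x <- data.frame(chrom = "1", pos = 1:5, ref = "A", alt = "G",
                  ac = c(3L, 5L, 4L, 10L, 200L),
                  hom = c(1L, 3L, 0L, 2L, 10L),
                  an = c(100L, 100L, 101L, 100L, 100L))
  split <- validate_site_counts(x)
  expect_equal(nrow(split$accepted) + nrow(split$rejected), nrow(x))
  expect_equal(split$accepted$pos, c(1L, 4L))      # AC=3,Hom=1 accepted
  expect_match(split$rejected$reason[1], "2\\*hom")  # AC=5,Hom=3 rejected
  expect_match(split$rejected$reason[2], "even")     # odd AN rejected
  expect_match(split$rejected$reason[3], "exceeds an")  # AC > AN rejected

  # reader surfaces the same split, and strict mode errors
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_counts(x, path)
  expect_warning(acc <- read_site_counts(path), "rejected")
  expect_equal(nrow(acc), 2L)
  expect_equal(nrow(attr(acc, "rejected")), 3L)
  expect_error(suppressWarnings(read_site_counts(path, strict = TRUE)),
               "rejected")
})

test_that("generator site counts pass the reader with zero rejections", {
  sites <- gen_reference_sites(500, runif(1000, 0, 0.05), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_counts(sites, path)
  acc <- read_site_counts(path)
  expect_equal(nrow(acc), 1000L)
  expect_equal(nrow(attr(acc, "rejected")), 0L)
})

test_that("predictor codes normalize through the per-tool synonym maps", {
  expect_equal(normalize_predictor(c("T", "D", ".", NA), "SIFT"),
               c("tolerated", "deleterious", "missing", "missing"))
  # PolyPhen 'P' (possibly damaging) is deleterious; MutationTaster 'P'
  # (polymorphism) is tolerated
  expect_equal(normalize_predictor("P", "PolyPhen2_HDIV"), "deleterious")
  expect_equal(normalize_predictor("P", "MutationTaster"), "tolerated")
  expect_equal(normalize_predictor(c("H", "M", "L"), "MutationAssessor"),
               c("deleterious", "deleterious", "tolerated"))
  expect_equal(normalize_predictor("U", "LRT"), "missing")
  expect_error(normalize_predictor("X", "SIFT"), "SIFT.*'X'")
})

test_that("ClinVar strings collapse to the most severe listed category", {
  expect_equal(normalize_clinvar("Likely Pathogenic/Pathogenic"),
               "pathogenic")
  expect_equal(normalize_clinvar("Likely benign/US"), "uncertain")
  expect_equal(normalize_clinvar(c("Benign", "Not provided", NA, "-")),
               c("benign", "not_provided", "absent", "absent"))
  expect_error(normalize_clinvar("Artifact"), "unrecognized")
})

test_that("annotation tables round-trip with raw codes normalized", {
  ann <- gen_annotated_variants(25, c("all_pass", "fail_cadd"), seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  for (col in c("chrom", "pos", "ref", "alt", "gene", "consequence",
                "clinvar", paste0("pred_", PREDICTOR_TOOLS))) {
    expect_identical(back[[col]], ann[[col]])
  }
  expect_equal(back$cadd_phred, ann$cadd_phred, tolerance = 1e-9)

  # a published-style row with compound ClinVar and raw tool codes
  hdr <- c("chrom\tpos\tref\talt\tgene\tconsequence\trsid\tcadd_phred\tSIFT\tclinvar",
           "1\t45797228\tC\tT\tMUTYH\tmissense\trs36053993\t29.4\tD\tLikely Pathogenic/Pathogenic")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, path2)
  row <- read_annotations(path2)
  expect_equal(row$clinvar, "pathogenic")
  expect_equal(row$clinvar_raw, "Likely Pathogenic/Pathogenic")
  expect_equal(row$cadd_phred, 29.4)
  expect_equal(row$pred_SIFT, "deleterious")
  expect_equal(row$pred_MetaLR, "missing")  # absent column -> missing calls
})

test_that("genotype_matrix rejects out-of-range dosages", {
  expect_error(genotype_matrix(matrix(c(0, 3), 1)), "dosages")
  gm <- genotype_matrix(matrix(c(0L, 1L, 2L, NA), 2))
  expect_s3_class(gm, "genotype_matrix")
})
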