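ann_row <- function(maf_1kg = 1e-4, maf_exac = 1e-4, maf_local = 0,
                    cadd = 25, gerp = 3, phastcons = 0.8, phylop = 4,
                    n_deleterious = 8, n_missing = 0, gene = "GENE01",
                    consequence = "missense") {
  x <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                  gene = gene, consequence = consequence,
                  rsid = "rs1", maf_thousand_genomes = maf_1kg,
                  maf_exac_nfe_nontcga = maf_exac, maf_local = maf_local,
                  cadd_phred = cadd, gerp = gerp, phastcons = phastcons,
                  phylop = phylop, clinvar = "absent",
                  clinvar_raw = NA_character_,
                  intol_esp = NA_real_, intol_exac = NA_real_,
                  intol_local = NA_real_, mis_z = NA_real_)
  calls <- c(rep("deleterious", n_deleterious),
             rep("tolerated", 10 - n_deleterious - n_missing),
             rep("missing", n_missing))
  for (i in seq_along(PREDICTOR_TOOLS)) {
    x[[paste0("pred_", PREDICTOR_TOOLS[i])]] <- calls[i]
  }
  x
}

test_that("the rarity filter requires MAF below cutoff in every source", {
  expect_equal(maf_filter(ann_row(1e-4, 5e-4, 0)), "pass")
  expect_equal(maf_filter(ann_row(maf_exac = 3.96e-3)), "fail")
  expect_equal(maf_filter(ann_row(maf_1kg = 0.001)), "fail")  # strict <
  # an absent source is treated as rare, no source at all is unevaluated
  expect_equal(maf_filter(ann_row(maf_1kg = NA, maf_exac = NA)), "pass")
  expect_equal(maf_filter(ann_row(maf_1kg = NA, maf_exac = NA,
                                  maf_local = NA)), "not_evaluated")
})

test_that("CADD filter is strict-greater with configurable missing policy", {
  expect_equal(cadd_filter(ann_row(cadd = 24.1)), "pass")
  expect_equal(cadd_filter(ann_row(cadd = 0.11)), "fail")
  expect_equal(cadd_filter(ann_row(cadd = 10.0)), "fail")
  expect_equal(cadd_filter(ann_row(cadd = NA)), "not_evaluated")
  expect_equal(cadd_filter(ann_row(cadd = NA), strict_missing = TRUE),
               "fail")
})

test_that("conservation voting honours per-tool thresholds", {
  v <- conservation_vote(ann_row(gerp = 2.1, phastcons = 0.2, phylop = 3.5))
  expect_equal(v$votes, 2)
  expect_equal(v$status, "pass")
  # GERP and PhastCons cutoffs are exclusive, PhyloP's is inclusive
  v0 <- conservation_vote(ann_row(gerp = 2.0, phastcons = 0.3, phylop = 2.9))
  expect_equal(v0$votes, 0)
  expect_equal(v0$status, "fail")
  v3 <- conservation_vote(ann_row(gerp = 2.0, phastcons = 0.3, phylop = 3.0))
  expect_equal(v3$votes, 1)
  miss <- conservation_vote(ann_row(gerp = NA, phastcons = NA, phylop = NA))
  expect_equal(miss$status, "not_evaluated")
  one <- conservation_vote(ann_row(gerp = 3, phastcons = NA, phylop = NA))
  expect_equal(one$available, 1)
  expect_equal(one$status, "fail")  # 1 vote of 1 available < 2 required
})

test_that("deleteriousness requires a strict majority of available tools", {
  expect_equal(deleteriousness_vote(ann_row(n_deleterious = 7))$status, "pass")
  expect_equal(deleteriousness_vote(ann_row(n_deleterious = 6))$status, "pass")
  expect_equal(deleteriousness_vote(ann_row(n_deleterious = 5))$status, "fail")
  d04 <- deleteriousness_vote(ann_row(n_deleterious = 0, n_missing = 6))
  expect_equal(d04$available, 4)
  expect_equal(d04$status, "fail")
  d34 <- deleteriousness_vote(ann_row(n_deleterious = 3, n_missing = 6))
  expect_equal(d34$status, "pass")  # 3 of 4 available
  none <- deleteriousness_vote(ann_row(n_deleterious = 0, n_missing = 10))
  expect_equal(none$status, "not_evaluated")
})

test_that("intolerance screen annotates without blocking by default", {
  v <- ann_row()
  v$mis_z <- -1.2
  expect_equal(intolerance_screen(v)$status, "pass")
  expect_equal(intolerance_screen(v, list(mis_z = 0))$status, "fail")
  # default config: cascade verdict identical with and without the data
  with_scores <- fcvpp_cascade(v, "GENE01")$audit$final
  v2 <- v; v2$mis_z <- NA_real_
  expect_identical(fcvpp_cascade(v2, "GENE01")$audit$final, with_scores)
})

test_that("the cascade recovers planted stage failures exactly", {
  mix <- c(rep("fail_maf", 3), rep("fail_cadd", 3),
           rep("fail_conservation", 2), rep("fail_deleteriousness", 2),
           rep("all_pass", 5))
  ann <- gen_annotated_variants(15, mix, seed = 61, genes = "GENE01")
  res <- fcvpp_cascade(ann, "GENE01")
  expect_equal(nrow(res$survivors), 5L)
  expect_equal(sum(res$audit$final == "fail"), 10L)
  # each planted failure fails its own stage and only that stage
  for (stage in c("maf", "cadd", "conservation", "deleteriousness")) {
    planted <- ann$profile == paste0("fail_", stage)
    expect_true(all(res$audit[[stage]][planted] == "fail"))
    others <- setdiff(c("maf", "cadd", "conservation", "deleteriousness"),
                      stage)
    for (o in others) expect_true(all(res$audit[[o]][planted] != "fail"))
  }
  # audit accounting: every in-scope variant appears exactly once
  expect_equal(nrow(res$audit), 15L)
  expect_equal(sort(res$audit$key),
               sort(variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)))
})

test_that("the cascade is a conjunction: stage order cannot matter", {
  ann <- gen_annotated_variants(60, c("all_pass", "fail_maf", "fail_cadd",
                                      "fail_conservation",
                                      "fail_deleteriousness"),
                                seed = 67, genes = c("GENE01", "GENE02"))
  res <- fcvpp_cascade(ann, c("GENE01", "GENE02"))
  # survivors equal the intersection of per-stage pass sets
  pass <- maf_filter(ann) != "fail" & cadd_filter(ann) != "fail" &
    conservation_vote(ann)$status != "fail" &
    deleteriousness_vote(ann)$status != "fail"
  expect_equal(variant_key(res$survivors$chrom, res$survivors$pos,
                           res$survivors$ref, res$survivors$alt),
               variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)[pass])
  # permuting the input changes nothing but row order
  perm <- sample(nrow(ann))
  res2 <- fcvpp_cascade(ann[perm, ], c("GENE01", "GENE02"))
  expect_equal(sort(res2$audit$key[res2$audit$final == "pass"]),
               sort(res$audit$key[res$audit$final == "pass"]))
})

test_that("tightening thresholds never enlarges the surviving set", {
  ann <- gen_annotated_variants(80, c("all_pass", "fail_cadd"), seed = 71,
                                genes = "GENE01")
  loose <- fcvpp_cascade(ann, "GENE01", cadd_threshold = 10)$survivors
  tight <- fcvpp_cascade(ann, "GENE01", cadd_threshold = 20)$survivors
  expect_true(all(variant_key(tight$chrom, tight$pos, tight$ref, tight$alt)
                  %in% variant_key(loose$chrom, loose$pos, loose$ref,
                                   loose$alt)))
})

test_that("scope: gene list and consequence class gate the cascade", {
  ann <- ann_row(gene = "ELSEWHERE")
  res <- fcvpp_cascade(ann, "GENE01")
  expect_equal(nrow(res$audit), 0L)  # excluded before any stage
  expect_error(fcvpp_cascade(ann, character(0)), "empty gene list")

  # LoF variants skip the conservation and deleteriousness votes
  lof <- ann_row(consequence = "stop_gain", n_deleterious = 0,
                 gerp = NA, phastcons = NA, phylop = NA)
  res_lof <- fcvpp_cascade(lof, "GENE01", consequence_class = "lof")
  expect_equal(res_lof$audit$final, "pass")
  expect_equal(res_lof$audit$deleteriousness, "not_evaluated")
  # ... but still face MAF and CADD
  lof2 <- ann_row(consequence = "splice_site", maf_exac = 0.01)
  expect_equal(fcvpp_cascade(lof2, "GENE01", "lof")$audit$final, "fail")
  # missense variants do not enter the LoF class and vice versa
  expect_equal(nrow(fcvpp_cascade(lof, "GENE01", "non_synonymous")$audit), 0L)
})
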