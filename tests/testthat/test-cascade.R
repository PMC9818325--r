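test_that("stage boundary semantics: quality, MAF and splice window", {
  cfg <- prioritization_config()
  # quality < 150 removed, exactly 150 passes
  expect_true(passes_stage(clean_variant(quality = 150), "i_quality", cfg))
  expect_false(passes_stage(clean_variant(quality = 149), "i_quality", cfg))
  # MAF strictly above 0.4% removed; 0.004 passes; absent (NA) passes
  expect_true(passes_stage(clean_variant(maf_supercontrols = 0.004),
                           "iv_supercontrol_maf", cfg))
  expect_false(passes_stage(clean_variant(maf_supercontrols = 0.0041),
                            "iv_supercontrol_maf", cfg))
  expect_true(passes_stage(clean_variant(maf_supercontrols = NA_real_),
                           "iv_supercontrol_maf", cfg))
  # population stage: ANY database above the cutoff fails
  expect_false(passes_stage(clean_variant(maf_1000g = 0.005),
                            "v_population_maf", cfg))
  expect_true(passes_stage(clean_variant(maf_gnomad = 0.004, maf_exac = 0.004),
                           "v_population_maf", cfg))
  # intronic within +/-2 bp survives stage viii; beyond is deep intronic
  intr <- function(off) clean_variant(consequence = "intronic",
                                      intron_offset = as.integer(off))
  expect_true(passes_stage(intr(2), "viii_deep_intronic", cfg))
  expect_false(passes_stage(intr(3), "viii_deep_intronic", cfg))
  expect_false(passes_stage(intr(-40), "viii_deep_intronic", cfg))
  expect_error(passes_stage(clean_variant(), "nonsense", cfg), "unknown")
})

test_that("retention rule: ClinVar route, truncation route, splice route", {
  # published carrier archetypes
  nbn <- clean_variant(gene = "NBN", consequence = "frameshift",
                       clinvar = "pathogenic")
  fh <- clean_variant(gene = "FH", consequence = "missense",
                      clinvar = "pathogenic")
  vus <- clean_variant(consequence = "missense", clinvar = "vus")
  out <- apply_filter_cascade(rbind(nbn, fh, vus))
  expect_equal(out$status, c("retained", "retained", "removed"))
  expect_equal(out$removal_stage[3], "final_not_pathogenic")
  # truncation route works with no ClinVar record at all
  out2 <- apply_filter_cascade(clean_variant(consequence = "stop_gained",
                                             clinvar = "none"))
  expect_equal(out2$status, "retained")
  # near-exon intronic counts as splice; CNV deletion as truncating
  out3 <- apply_filter_cascade(rbind(
    clean_variant(consequence = "intronic", intron_offset = 2L),
    clean_variant(consequence = "canonical_splice", intron_offset = -1L),
    clean_variant(consequence = "cnv_deletion")))
  expect_equal(out3$status, rep("retained", 3))
  # CNV duplication has no truncation route, needs ClinVar
  out4 <- apply_filter_cascade(rbind(
    clean_variant(consequence = "cnv_duplication", clinvar = "none"),
    clean_variant(consequence = "cnv_duplication", clinvar = "pathogenic")))
  expect_equal(out4$status, c("removed", "retained"))
})

test_that("one constructed variant per stage is removed at exactly that stage", {
  set.seed(11)
  labels <- c(cascade_stages(), "final_not_pathogenic")
  batch <- do.call(rbind, lapply(labels, function(s) {
    make_nuisance_variant(s, gene = "NBN", sample_id = "S1",
                          variant_id = paste0("nv:", s))
  }))
  out <- apply_filter_cascade(batch)
  expect_true(all(out$status == "removed"))
  expect_equal(out$removal_stage, labels)
  aud <- audit_summary(out)
  expect_equal(aud$removed, rep(1L, length(labels)))
  expect_identical(attr(aud, "retained"), 0L)
})

test_that("cascade equals the brute-force first-failure oracle on random batches", {
  set.seed(2024)
  vars <- annotated_variants(random_variants(1000))
  out <- apply_filter_cascade(vars)
  for (i in seq_len(nrow(vars))) {
    expected <- oracle_outcome(vars[i, ])
    expect_identical(out$status[i], expected$status)
    expect_identical(out$removal_stage[i], expected$stage)
  }
  # membership is order-free: retained set == conjunction of all predicates
  conj <- vapply(seq_len(nrow(vars)), function(i) {
    all(vapply(cascade_stages(), function(s) passes_stage(vars[i, ], s),
               logical(1)))
  }, logical(1))
  final <- vapply(seq_len(nrow(vars)), function(i) {
    oracle_outcome(vars[i, ])$status == "retained"
  }, logical(1))
  expect_identical(out$status == "retained", conj & final)
})

test_that("cascade is idempotent and every input gets exactly one outcome", {
  set.seed(7)
  vars <- annotated_variants(random_variants(400))
  out <- apply_filter_cascade(vars)
  expect_identical(nrow(out), nrow(vars))
  expect_identical(out$variant_id, vars$variant_id)  # order preserved
  kept <- retained_variants(out)
  again <- apply_filter_cascade(kept)
  expect_true(all(again$status == "retained"))
  # exactly one removal stage per removed variant, none for retained
  expect_true(all(is.na(out$removal_stage) == (out$status == "retained")))
})

test_that("tightening thresholds never grows the retained set", {
  set.seed(99)
  vars <- annotated_variants(random_variants(600))
  base <- apply_filter_cascade(vars)
  kept_base <- base$variant_id[base$status == "retained"]
  for (cfg in list(prioritization_config(maf_max = 0.001),
                   prioritization_config(quality_min = 400),
                   prioritization_config(quality_min = 300, maf_max = 0.002))) {
    out <- apply_filter_cascade(vars, cfg)
    kept <- out$variant_id[out$status == "retained"]
    expect_true(all(kept %in% kept_base))
  }
})

test_that("audit summary counts reconcile with outcomes", {
  empty <- apply_filter_cascade(annotated_variants(random_variants(0)))
  aud0 <- audit_summary(empty)
  expect_true(all(aud0$removed == 0L))
  expect_identical(attr(aud0, "retained"), 0L)

  set.seed(5)
  out <- apply_filter_cascade(annotated_variants(random_variants(300)))
  aud <- audit_summary(out)
  expect_identical(sum(aud$removed), sum(out$status == "removed"))
  expect_identical(attr(aud, "retained") + sum(aud$removed), nrow(out))
})
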