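small_panel <- function() {
  gene_panel(c(NBN = "established", FH = "established", RAD50 = "candidate",
               MRE11 = "candidate"),
             list(MRN = c("MRE11", "RAD50", "NBN")))
}

test_that("zero rates give an empty variant table but a full phenotype table", {
  cfg <- cohort_config(n_cases = 5, n_controls = 7,
                       carrier_prob_cases = c(NBN = 0),
                       carrier_prob_controls = c(NBN = 0),
                       nuisance_rate = numeric(0), seed = 3,
                       panel = small_panel())
  sim <- simulate_cohort(cfg)
  expect_identical(nrow(sim$variants), 0L)
  expect_identical(nrow(sim$phenotypes), 12L)
  expect_identical(anyDuplicated(sim$phenotypes$sample_id), 0L)
  expect_identical(table(sim$phenotypes$group)[["case"]], 5L)
})

test_that("a fixed seed reproduces the cohort byte-identically", {
  cfg <- cohort_config(n_cases = 30, n_controls = 40, seed = 17)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # and the RNG stream of the caller is left untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(simulate_cohort(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("simulated cohorts are fully recovered by the cascade", {
  cfg <- cohort_config(n_cases = 120, n_controls = 150, seed = 29,
                       panel = small_panel(),
                       carrier_prob_cases = c(NBN = 0.05, RAD50 = 0.04),
                       carrier_prob_controls = c(NBN = 0.01, RAD50 = 0.01),
                       nuisance_rate = stats::setNames(
                         rep(0.4, 11), c(cascade_stages(),
                                         "final_not_pathogenic")))
  sim <- simulate_cohort(cfg)
  out <- apply_filter_cascade(sim$variants)
  kept <- out$variant_id[out$status == "retained"]
  # retained set == planted carriers, no nuisance leaks
  expect_setequal(kept, sim$truth$planted$variant_id)
  expect_length(intersect(kept, sim$truth$nuisance$variant_id), 0)
  # every nuisance variant removed at its intended stage
  removed <- out[out$status == "removed", ]
  got <- stats::setNames(removed$removal_stage, removed$variant_id)
  expect_identical(unname(got[sim$truth$nuisance$variant_id]),
                   sim$truth$nuisance$stage)
  # phenotype carrier flags agree with the planted ground truth
  mrn_carriers <- unique(sim$truth$planted$sample_id[
    sim$truth$planted$gene %in% c("MRE11", "RAD50", "NBN")])
  expect_setequal(sim$phenotypes$sample_id[sim$phenotypes$carrier_MRN],
                  mrn_carriers)
})

test_that("constructed carrier variants always survive; nuisance never do", {
  set.seed(41)
  for (i in 1:25) {
    cv <- make_carrier_variant("NBN", "S1", sprintf("v%d", i))
    expect_identical(apply_filter_cascade(cv)$status, "retained")
  }
  for (stage in c(cascade_stages(), "final_not_pathogenic")) {
    for (i in 1:5) {
      nv <- make_nuisance_variant(stage, "RAD50", "S1", "nv")
      out <- apply_filter_cascade(nv)
      expect_identical(out$status, "removed")
      expect_identical(out$removal_stage, stage)
    }
  }
  expect_error(make_nuisance_variant("xi_bogus", "NBN"), "unknown")
})

test_that("configured carrier frequency is recovered at n = 10,000", {
  cfg <- cohort_config(n_cases = 10000, n_controls = 0,
                       carrier_prob_cases = c(NBN = 0.012),
                       carrier_prob_controls = numeric(0),
                       nuisance_rate = numeric(0), seed = 1,
                       panel = small_panel())
  sim <- simulate_cohort(cfg)
  k <- length(unique(sim$truth$planted$sample_id))
  expect_gte(k, qbinom(0.025, 10000, 0.012))
  expect_lte(k, qbinom(0.975, 10000, 0.012))
})

test_that("binomial-interval coverage holds across 20 seeds", {
  inside <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_cases = 10000, n_controls = 0,
                         carrier_prob_cases = c(NBN = 0.012),
                         carrier_prob_controls = numeric(0),
                         nuisance_rate = numeric(0), seed = s,
                         panel = small_panel())
    sim <- simulate_cohort(cfg)
    k <- nrow(sim$truth$planted)
    k >= qbinom(0.025, 10000, 0.012) && k <= qbinom(0.975, 10000, 0.012)
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_cases = -1), "non-negative")
  expect_error(cohort_config(carrier_prob_cases = c(NBN = 1.5)),
               "probabilities")
  expect_error(cohort_config(carrier_prob_cases = c(NOT_A_GENE = 0.1)),
               "NOT_A_GENE")
  expect_error(cohort_config(nuisance_rate = c(bogus_stage = 1)), "bogus")
  expect_error(cohort_config(survival_params = list(
    hazard = -1, carrier_hazard_ratio = 1, horizon_months = 10)), "survival")
})
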