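make_pheno <- function(n, carrier_frac = 0.5, age_shift = 0, seed = 1) {
  set.seed(seed)
  carrier <- seq_len(n) <= round(n * carrier_frac)
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)), group = "case",
    carrier_established = carrier,
    age_at_dx = round(rnorm(n, 63, 8)) + ifelse(carrier, age_shift, 0),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.77, 0.23)),
    etiology = sample(c("alcoholic", "viral", "NASH"), n, replace = TRUE),
    diabetes = runif(n) < 0.4,
    survival_months = rexp(n, 0.01), event = runif(n) < 0.7,
    stringsAsFactors = FALSE)
}

test_that("test dispatch: chi-square for categories, Mann-Whitney for continuous", {
  cmp <- compare_groups(make_pheno(400), "established")
  expect_s3_class(cmp, "group_comparison")
  expect_identical(cmp$test[cmp$characteristic == "age_at_dx"], "mann_whitney")
  expect_identical(cmp$test[cmp$characteristic == "sex"], "chi_square")
  expect_identical(cmp$test[cmp$characteristic == "etiology"], "chi_square")
  expect_identical(cmp$test[cmp$characteristic == "diabetes"], "chi_square")
  cmp_t <- compare_groups(make_pheno(400), "established",
                          continuous_test = "t_test")
  expect_identical(cmp_t$test[cmp_t$characteristic == "age_at_dx"], "t_test")
  expect_error(compare_groups(make_pheno(10), "MRN"), "carrier_MRN")
})

test_that("identical distributions rarely reject across 20 seeds", {
  frac_signif <- vapply(1:20, function(s) {
    cmp <- compare_groups(make_pheno(1000, seed = s), "established")
    mean(cmp$p_value[cmp$testable] < 0.05)
  }, numeric(1))
  # all p > 0.05 in at least 90% of seeds would be strict with 5 tests each;
  # require the family-level false-positive fraction to stay near nominal
  expect_gte(mean(vapply(1:20, function(s) {
    all(compare_groups(make_pheno(1000, seed = s),
                       "established")$p_value > 0.05, na.rm = TRUE)
  }, logical(1))), 0.6)
  expect_lte(mean(frac_signif), 0.10)
})

test_that("a planted 10-year age shift is detected with high power", {
  cmp <- compare_groups(make_pheno(1000, age_shift = 10, seed = 4),
                        "established")
  expect_lt(cmp$p_value[cmp$characteristic == "age_at_dx"], 1e-3)
})

test_that("degenerate characteristics are flagged untestable, not errors", {
  ph <- make_pheno(50)
  ph$cirrhosis <- TRUE  # constant in both groups
  cmp <- compare_groups(ph, "established", characteristics = "cirrhosis")
  expect_false(cmp$testable)
  expect_true(is.na(cmp$p_value))
  # empty stratum: nobody is a carrier
  ph$carrier_established <- FALSE
  cmp2 <- compare_groups(ph, "established", characteristics = "age_at_dx")
  expect_false(cmp2$testable)
})

test_that("Kaplan-Meier estimator: closed forms and a hand-computed table", {
  # all censored: survival identically 1
  km <- kaplan_meier(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(km$survival == 1))
  # all events, no ties: empirical survival function
  km2 <- kaplan_meier(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km2$survival, c(1, 2 / 3, 1 / 3, 0))
  # six subjects, events at 2, 5, 7, censored at 4, 9, 11 (hand product-limit:
  # 5/6, then 5/6*3/4, then 5/8*2/3)
  km3 <- kaplan_meier(c(2, 4, 5, 7, 9, 11),
                      c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  s <- function(t) km3$survival[max(which(km3$time <= t))]
  expect_equal(s(2), 5 / 6)
  expect_equal(s(5), 5 / 8)
  expect_equal(s(7), 5 / 12)
  expect_equal(s(11), 5 / 12)
  # monotone, bounded, starts at 1
  expect_true(all(diff(km3$survival) <= 0))
  expect_equal(km3$survival[1], 1)
  expect_error(kaplan_meier(numeric(0), logical(0)), "empty")
})

test_that("log-rank: identical groups, invariances and error cases", {
  t0 <- c(1, 3, 5, 7, 9, 11); e0 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  # duplicated data in two groups: statistic 0, p = 1
  expect_equal(logrank_p(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 6)), 1)
  # invariant to group relabeling and to time translation
  set.seed(8)
  tt <- rexp(60, 0.1); ee <- runif(60) < 0.6
  gg <- rep(c("x", "y"), 30)
  p1 <- logrank_p(tt, ee, gg)
  expect_equal(logrank_p(tt, ee, ifelse(gg == "x", "y", "x")), p1)
  expect_equal(logrank_p(tt + 100, ee, gg), p1)
  expect_error(logrank_p(tt, ee, rep("x", 60)), "two groups")
  expect_error(logrank_p(tt, ee[-1], gg), "equal length")
})

test_that("log-rank p agrees with a permutation oracle", {
  set.seed(15)
  n <- 60
  tt <- c(rexp(n / 2, 0.08), rexp(n / 2, 0.12))
  ee <- runif(n) < 0.75
  gg <- rep(c("a", "b"), each = n / 2)
  p_asym <- logrank_p(tt, ee, gg)
  chisq_of <- function(labels) {
    survival::survdiff(survival::Surv(tt, ee) ~ labels)$chisq
  }
  obs <- chisq_of(gg)
  perm <- vapply(1:10000, function(i) chisq_of(sample(gg)), numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_asym - p_perm), 0.03)
})
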