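#' Compare carriers vs non-carriers on clinical characteristics
#'
#' For a chosen carrier flag (established-CPG, candidate-CPG, MRN-complex or
#' any), tests each demographic/tumor characteristic between carriers and
#' non-carriers: categorical (including logical) characteristics with the
#' Pearson chi-square test, continuous characteristics with the Mann-Whitney
#' test by default (Kruskal-Wallis when the grouping has more than two
#' levels; Student's t-test selectable). All tests two-sided. A
#' characteristic constant in the pooled data, or a grouping with an empty
#' stratum, is marked untestable rather than failing the run.
#'
#' @param pheno Phenotype data.frame as produced by [simulate_cohort()] /
#'   [read_phenotype_table()].
#' @param flag Which carrier flag defines the groups: `"established"`,
#'   `"candidate"`, `"MRN"` or `"any"` (expects a `carrier_<flag>` column).
#' @param characteristics Columns to compare; default: every demographic and
#'   tumor column present, i.e. all columns except identifiers, group,
#'   carrier flags and survival.
#' @param continuous_test `"mann_whitney"` (default) or `"t_test"`.
#' @param alpha Significance threshold recorded in the report (not asserted).
#' @return data.frame of class `group_comparison`: one row per
#'   characteristic with `test`, `statistic`, `p_value`, `testable` and group
#'   summary strings.
#' @export
compare_groups <- function(pheno, flag = c("established", "candidate",
                                           "MRN", "any"),
                           characteristics = NULL,
                           continuous_test = c("mann_whitney", "t_test"),
                           alpha = 0.05) {
  flag <- match.arg(flag)
  continuous_test <- match.arg(continuous_test)
  col <- paste0("carrier_", flag)
  if (!col %in% names(pheno)) {
    stop_cfg("phenotype table has no column '%s'", col)
  }
  grp <- factor(ifelse(pheno[[col]], "carrier", "non_carrier"),
                levels = c("carrier", "non_carrier"))
  if (is.null(characteristics)) {
    skip <- c("sample_id", "group", "survival_months", "event",
              grep("^carrier_", names(pheno), value = TRUE))
    characteristics <- setdiff(names(pheno), skip)
  }
  rows <- lapply(characteristics, function(ch) {
    x <- pheno[[ch]]
    if (is.null(x)) stop_cfg("unknown characteristic: %s", ch)
    compare_one(ch, x, grp, continuous_test)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "flag") <- flag
  attr(out, "alpha") <- alpha
  attr(out, "n_carrier") <- sum(grp == "carrier", na.rm = TRUE)
  attr(out, "n_non_carrier") <- sum(grp == "non_carrier", na.rm = TRUE)
  class(out) <- c("group_comparison", "data.frame")
  out
}

compare_one <- function(name, x, grp, continuous_test) {
  untestable <- function(test) {
    data.frame(characteristic = name, type = if (is.numeric(x)) "continuous"
               else "categorical", test = test, statistic = NA_real_,
               p_value = NA_real_, testable = FALSE,
               carriers = summarise_values(x[grp == "carrier"]),
               non_carriers = summarise_values(x[grp == "non_carrier"]),
               stringsAsFactors = FALSE)
  }
  if (any(table(grp) == 0L)) return(untestable("none"))
  if (is.numeric(x) && !is.logical(x)) {
    nlev <- nlevels(droplevels(grp))
    if (length(unique(x[!is.na(x)])) < 2L) return(untestable("none"))
    if (nlev > 2L) {
      ht <- stats::kruskal.test(x ~ grp)
    } else if (continuous_test == "t_test") {
      ht <- stats::t.test(x ~ grp)
    } else {
      ht <- stats::wilcox.test(x ~ grp, exact = FALSE)
    }
    test_name <- switch(continuous_test, t_test = "t_test",
                        mann_whitney = "mann_whitney")
    if (nlev > 2L) test_name <- "kruskal_wallis"
    return(data.frame(characteristic = name, type = "continuous",
                      test = test_name,
                      statistic = unname(ht$statistic), p_value = ht$p.value,
                      testable = TRUE,
                      carriers = summarise_values(x[grp == "carrier"]),
                      non_carriers = summarise_values(x[grp == "non_carrier"]),
                      stringsAsFactors = FALSE))
  }
  x <- factor(x)
  if (nlevels(droplevels(x[!is.na(x)])) < 2L) return(untestable("chi_square"))
  tab <- table(grp, x)
  if (any(rowSums(tab) == 0L)) return(untestable("chi_square"))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  data.frame(characteristic = name, type = "categorical", test = "chi_square",
             statistic = unname(ht$statistic), p_value = ht$p.value,
             testable = TRUE,
             carriers = summarise_values(x[grp == "carrier"]),
             non_carriers = summarise_values(x[grp == "non_carrier"]),
             stringsAsFactors = FALSE)
}

summarise_values <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("n=0")
  if (is.numeric(x) && !is.logical(x)) {
    sprintf("median %.1f (range %.1f-%.1f)", stats::median(x), min(x), max(x))
  } else if (is.logical(x)) {
    sprintf("%d/%d (%.1f%%)", sum(x), length(x),
            round_half_up(100 * mean(x), 1))
  } else {
    tab <- table(x)
    paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " ")
  }
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Carrier (%s) vs non-carrier comparison: %d vs %d subjects\n",
              attr(x, "flag"), attr(x, "n_carrier"),
              attr(x, "n_non_carrier")))
  disp <- data.frame(characteristic = x$characteristic, test = x$test,
                     p = ifelse(x$testable, format_p_value(x$p_value),
                                "untestable"),
                     stringsAsFactors = FALSE)
  print(disp, row.names = FALSE)
  cat(sprintf("(significance threshold %.2f, two-sided; no multiplicity adjustment)\n",
              attr(x, "alpha")))
  invisible(x)
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Step-function coordinates of the product-limit estimator, starting at
#' `(0, 1)`. Censored subjects at a time remain at risk for events at that
#' time (standard tie convention). Computed via [survival::survfit()].
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `survival`.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop_cfg("empty survival input")
  if (length(times) != length(events)) {
    stop_cfg("times and events must have equal length")
  }
  if (any(is.na(times)) || any(times < 0)) {
    stop_cfg("times must be non-negative and non-missing")
  }
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = c(0, fit$time),
             n_risk = c(length(times), fit$n.risk),
             n_event = c(0, fit$n.event),
             survival = c(1, fit$surv))
}

#' Log-rank test p-value
#'
#' Two-sided p-value of the standard log-rank chi-square statistic with
#' `(number of groups - 1)` degrees of freedom, via [survival::survdiff()].
#'
#' @inheritParams kaplan_meier
#' @param group_labels Group membership vector, at least two non-empty groups.
#' @return p-value in \[0, 1\].
#' @export
logrank_p <- function(times, events, group_labels) {
  if (length(times) != length(events) ||
      length(times) != length(group_labels)) {
    stop_cfg("times, events and group_labels must have equal length")
  }
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop_cfg("log-rank test needs at least two groups")
  if (any(table(g) == 0L)) stop_cfg("log-rank test: empty group")
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ g)
  unname(stats::pchisq(sd$chisq, df = nlevels(g) - 1L, lower.tail = FALSE))
}
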