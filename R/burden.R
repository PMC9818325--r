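#' 2x2 carrier contingency table
#'
#' Cell layout for case-control burden testing: `a` case carriers, `b` case
#' non-carriers, `c` control carriers, `d` control non-carriers.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Named numeric vector of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!vapply(cells, is_count, logical(1)))) {
    stop_cfg("contingency table cells must be non-negative integers")
  }
  structure(as.numeric(cells), names = names(cells),
            class = "contingency_table")
}

as_ct <- function(t) {
  if (inherits(t, "contingency_table")) return(t)
  if (is.numeric(t) && length(t) == 4L) {
    return(contingency_table(t[[1]], t[[2]], t[[3]], t[[4]]))
  }
  stop_cfg("expected a contingency_table or numeric vector of length 4 (a,b,c,d)")
}

#' Odds ratio of a 2x2 carrier table
#'
#' Cross-product ratio (a*d)/(b*c). Undefined (`NA`) when any cell is zero —
#' reported as "n.d." in rendered tables.
#'
#' @param t A [contingency_table()] (or numeric `c(a, b, c, d)`).
#' @return Positive number, or `NA_real_` when undefined.
#' @export
odds_ratio <- function(t) {
  t <- as_ct(t)
  if (any(t == 0)) return(NA_real_)
  unname((t["a"] * t["d"]) / (t["b"] * t["c"]))
}

#' Woolf (logit) confidence interval for the odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the two-sided
#' standard-normal quantile for `level`. Undefined when any cell is zero.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Named numeric `c(low, high)`, or `c(NA, NA)` when undefined.
#' @export
woolf_ci <- function(t, level = 0.95) {
  t <- as_ct(t)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_cfg("confidence level must be in (0, 1)")
  }
  if (any(t == 0)) return(c(low = NA_real_, high = NA_real_))
  or <- odds_ratio(t)
  se <- sqrt(sum(1 / t))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = or * exp(-z * se), high = or * exp(z * se))
}

#' Pearson chi-square p-value for a 2x2 table
#'
#' Two-sided p-value from the Pearson statistic
#' `n * (ad - bc)^2 / ((a+b) (c+d) (a+c) (b+d))` referred to chi-square with
#' one degree of freedom, without continuity correction (the convention that
#' reproduces the published carrier-frequency comparisons).
#'
#' @inheritParams odds_ratio
#' @return p-value in \[0, 1\]; `NA_real_` when a table margin is zero.
#' @export
pearson_chi2_p <- function(t) {
  t <- as_ct(t)
  n <- sum(t)
  if (n == 0) stop_cfg("empty contingency table")
  m <- c(t["a"] + t["b"], t["c"] + t["d"], t["a"] + t["c"], t["b"] + t["d"])
  if (any(m == 0)) return(NA_real_)
  stat <- n * (t["a"] * t["d"] - t["b"] * t["c"])^2 / prod(m)
  unname(stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher's exact p-value for a 2x2 table
#'
#' Optional alternative to [pearson_chi2_p()] for small cells; delegates to
#' [stats::fisher.test()] (two-sided).
#'
#' @inheritParams odds_ratio
#' @return p-value in \[0, 1\].
#' @export
fisher_exact_p <- function(t) {
  t <- as_ct(t)
  stats::fisher.test(matrix(t, nrow = 2, byrow = TRUE))$p.value
}

#' Case-control burden table over genes, classes and gene sets
#'
#' For every gene with at least one case carrier (grouped by panel class),
#' every configured gene set, and the per-class "all carriers" rows, builds
#' the 2x2 distinct-carrier table and computes the odds ratio, Woolf CI and
#' Pearson chi-square p (or Fisher's exact p with `test = "fisher"`). Rows
#' with a zero cell are flagged `defined = FALSE` and render as "n.d.".
#'
#' @param cases,controls `carrier_matrix` objects (see [classify_retained()],
#'   [counts_to_carrier_matrix()]).
#' @param n_cases,n_controls Cohort sizes; must be at least the observed
#'   carrier counts.
#' @param panel A [gene_panel()].
#' @param level Confidence level for the CI.
#' @param test `"pearson"` (default) or `"fisher"`.
#' @param bonferroni Add a Bonferroni-adjusted p column over the per-gene rows
#'   (exploratory; the reproduced analysis applied no correction).
#' @return data.frame of class `burden_table` with columns `label`, `type`
#'   (gene/class/set), `class`, `case_carriers`, `case_pct`,
#'   `control_carriers`, `control_pct`, `or`, `ci_low`, `ci_high`, `p_value`,
#'   `defined` (and `p_bonferroni` if requested).
#' @export
burden_table <- function(cases, controls, n_cases, n_controls, panel,
                         level = 0.95, test = c("pearson", "fisher"),
                         bonferroni = FALSE) {
  stopifnot(inherits(cases, "carrier_matrix"),
            inherits(controls, "carrier_matrix"),
            inherits(panel, "gene_panel"))
  test <- match.arg(test)
  if (!is_count(n_cases) || !is_count(n_controls)) {
    stop_cfg("n_cases and n_controls must be non-negative integers")
  }
  pfun <- if (test == "pearson") pearson_chi2_p else fisher_exact_p

  one_row <- function(label, type, class, a, c) {
    if (a > n_cases || c > n_controls) {
      stop_cfg("carrier count exceeds cohort size for '%s'", label)
    }
    t <- contingency_table(a, n_cases - a, c, n_controls - c)
    or <- odds_ratio(t)
    ci <- woolf_ci(t, level)
    data.frame(label = label, type = type, class = class,
               case_carriers = a,
               case_pct = round_half_up(100 * a / n_cases, 1),
               control_carriers = c,
               control_pct = round_half_up(100 * c / n_controls, 1),
               or = or, ci_low = ci[["low"]], ci_high = ci[["high"]],
               p_value = if (is.na(or)) NA_real_ else pfun(t),
               defined = !is.na(or),
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (cl in c("established", "candidate")) {
    genes <- names(panel$genes)[panel$genes == cl]
    genes <- genes[vapply(genes, function(g) length(cases$per_gene[[g]]) > 0,
                          logical(1))]
    for (g in genes) {
      rows[[length(rows) + 1L]] <-
        one_row(g, "gene", cl, length(cases$per_gene[[g]]),
                length(controls$per_gene[[g]]))
    }
    rows[[length(rows) + 1L]] <-
      one_row(paste0("all_", cl), "class", cl,
              length(cases$per_class[[cl]]), length(controls$per_class[[cl]]))
  }
  for (s in names(panel$gene_sets)) {
    rows[[length(rows) + 1L]] <-
      one_row(s, "set", NA_character_, length(cases$per_set[[s]]),
              length(controls$per_set[[s]]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bonferroni) {
    gene_rows <- out$type == "gene"
    out$p_bonferroni <- NA_real_
    out$p_bonferroni[gene_rows] <- stats::p.adjust(out$p_value[gene_rows],
                                                   method = "bonferroni")
  }
  attr(out, "n_cases") <- n_cases
  attr(out, "n_controls") <- n_controls
  attr(out, "test") <- test
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Render a p-value the way the reproduced report prints it
#'
#' Three decimals (half-up) below 0.05, one decimal otherwise; values that
#' would round to zero render as `"<0.001"` and `NA` as `"n.d."`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(is.na(p), "n.d.",
         ifelse(p < 0.0005, "<0.001",
                ifelse(p < 0.05, sprintf("%.3f", round_half_up(p, 3)),
                       sprintf("%.1f", round_half_up(p, 1)))))
}

#' @export
print.burden_table <- function(x, ...) {
  nca <- attr(x, "n_cases"); nco <- attr(x, "n_controls")
  cat(sprintf("Carrier burden, %d cases vs %d controls (%s test)\n",
              nca, nco, attr(x, "test")))
  disp <- data.frame(
    label = x$label,
    cases = sprintf("%d (%.1f)", x$case_carriers, x$case_pct),
    controls = sprintf("%d (%.1f)", x$control_carriers, x$control_pct),
    `OR (95% CI)` = ifelse(x$defined,
                           sprintf("%.1f (%.2f-%.2f)",
                                   round_half_up(x$or, 1),
                                   round_half_up(x$ci_low, 2),
                                   round_half_up(x$ci_high, 2)),
                           "n.d."),
    p = format_p_value(x$p_value),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}
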