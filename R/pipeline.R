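#' End-to-end pipeline: prioritize, count carriers, burden test, clinical
#'
#' Orchestrates the full analysis on already-annotated inputs: applies the
#' prioritization cascade to the case variant table, builds the distinct-sample
#' carrier matrix, derives the control carrier matrix (from a control variant
#' table run through the same cascade, or from published per-gene carrier
#' counts), computes the case-control burden table, and — when a phenotype
#' table is supplied — the carrier/non-carrier clinical comparison and
#' Kaplan-Meier/log-rank survival contrast per carrier flag. All outputs are
#' written under `out_dir`; inputs are never modified.
#'
#' @param variants Case variant table: path (TSV/VCF per `dialect`) or an
#'   [annotated_variants()] table.
#' @param panel A [gene_panel()] or path to a panel YAML/JSON.
#' @param n_cases,n_controls Cohort sizes.
#' @param control_variants Optional control variant table (path or object).
#' @param control_counts Optional named per-gene distinct-carrier counts for
#'   controls (used when `control_variants` is absent).
#' @param pheno Optional phenotype table (path or data.frame).
#' @param config A [prioritization_config()].
#' @param out_dir Output directory, created if needed.
#' @param dialect Input dialect for variant paths.
#' @return Invisibly, a list of class `pipeline_result` with elements
#'   `outcomes`, `audit`, `carriers_cases`, `carriers_controls`, `burden`,
#'   `clinical` (possibly `NULL`) and `files` (paths written).
#' @export
run_pipeline <- function(variants, panel, n_cases, n_controls,
                         control_variants = NULL, control_counts = NULL,
                         pheno = NULL, config = prioritization_config(),
                         out_dir = tempfile("cpgcascade_run_"),
                         dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (is.character(variants)) variants <- read_variant_table(variants, dialect)
  if (is.character(panel)) panel <- read_gene_panel(panel)
  stopifnot(inherits(panel, "gene_panel"))
  if (is.character(pheno)) pheno <- read_phenotype_table(pheno)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files[[name]] <<- path
    path
  }

  # stage 1: prioritization cascade + audit trail
  outcomes <- apply_filter_cascade(variants, config)
  audit <- audit_summary(outcomes)
  kept <- retained_variants(outcomes)
  emit("retained_variants.tsv", function(p) write_variant_table(kept, p))
  emit("audit.tsv", function(p) {
    utils::write.table(rbind(audit, data.frame(stage = "retained",
                                               removed = attr(audit, "retained"))),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  # stage 2: distinct-sample carrier accounting
  carriers_cases <- classify_retained(outcomes, panel)

  carriers_controls <- if (!is.null(control_variants)) {
    if (is.character(control_variants)) {
      control_variants <- read_variant_table(control_variants, dialect)
    }
    classify_retained(apply_filter_cascade(control_variants, config), panel)
  } else if (!is.null(control_counts)) {
    counts_to_carrier_matrix(control_counts, panel)
  } else {
    counts_to_carrier_matrix(stats::setNames(integer(0), character(0)), panel)
  }

  # stage 3: case-control burden
  burden <- burden_table(carriers_cases, carriers_controls,
                         n_cases = n_cases, n_controls = n_controls,
                         panel = panel)
  emit("burden.tsv", function(p) {
    utils::write.table(as.data.frame(burden), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  })
  emit("burden.json", function(p) {
    jsonlite::write_json(as.data.frame(burden), p, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  })

  # stage 4: clinical comparison (cases only; needs carriers on both sides)
  clinical <- NULL
  if (!is.null(pheno)) {
    cases_pheno <- pheno[pheno$group == "case", , drop = FALSE]
    if (length(carriers_cases$all) == 0L || nrow(cases_pheno) == 0L) {
      message("clinical stage skipped: no retained carriers or no case phenotypes")
    } else {
      clinical <- clinical_report(cases_pheno)
      emit("clinical.json", function(p) {
        jsonlite::write_json(clinical, p, auto_unbox = TRUE, digits = NA,
                             na = "null", pretty = TRUE)
      })
    }
  }

  emit("run_log.txt", function(p) {
    writeLines(c(
      sprintf("cpgcascade %s", as.character(utils::packageVersion("cpgcascade"))),
      sprintf("quality_min=%s maf_max=%s splice_window_bp=%d",
              format(config$quality_min), format(config$maf_max),
              config$splice_window_bp),
      sprintf("n_cases=%d n_controls=%d", n_cases, n_controls),
      sprintf("variants_in=%d retained=%d", nrow(outcomes),
              attr(audit, "retained")),
      sprintf("panel_genes=%d", length(panel$genes))), p)
  })

  structure(list(outcomes = outcomes, audit = audit,
                 carriers_cases = carriers_cases,
                 carriers_controls = carriers_controls,
                 burden = burden, clinical = clinical, files = files),
            class = "pipeline_result")
}

clinical_report <- function(cases_pheno) {
  flags <- intersect(c("established", "candidate", "MRN", "any"),
                     sub("^carrier_", "",
                         grep("^carrier_", names(cases_pheno), value = TRUE)))
  report <- list()
  for (fl in flags) {
    col <- paste0("carrier_", fl)
    if (!any(cases_pheno[[col]]) || all(cases_pheno[[col]])) next
    cmp <- compare_groups(cases_pheno, fl)
    entry <- list(comparison = as.data.frame(cmp))
    if (all(c("survival_months", "event") %in% names(cases_pheno))) {
      entry$logrank_p <- logrank_p(cases_pheno$survival_months,
                                   cases_pheno$event, cases_pheno[[col]])
      km <- function(sel) kaplan_meier(cases_pheno$survival_months[sel],
                                       cases_pheno$event[sel])
      entry$km_carrier <- km(cases_pheno[[col]])
      entry$km_non_carrier <- km(!cases_pheno[[col]])
    }
    report[[fl]] <- entry
  }
  report
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run\n")
  print(x$outcomes)
  print(x$carriers_cases)
  cat(sprintf("outputs: %s\n", paste(names(x$files), collapse = ", ")))
  invisible(x)
}
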