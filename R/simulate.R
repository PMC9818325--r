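# Published distinct-carrier counts per gene (cases n=334, controls n=1662);
# the generator's default carrier probabilities are these frequencies.
default_case_counts <- function() {
  c(PMS2 = 1, NBN = 4, FH = 1, RET = 1,
    DMBT1 = 3, RAD50 = 3, ATRIP = 2, BLM = 2, ERCC2 = 2, LIG3 = 2, MSH3 = 2,
    SLX4 = 2, AXIN1 = 1, ERCC5 = 1, ERCC6 = 1, EXO1 = 1, FANCA = 1,
    FANCD2 = 1, FANCG = 1, HOXB13 = 1, MCPH1 = 1, MDC1 = 1, MLH3 = 1,
    MMP8 = 1, NHEJ1 = 1, PIK3CG = 1, PMS1 = 1, RAD1 = 1, RECQL5 = 1,
    SBDS = 1, SETX = 1, SMARCA4 = 1, TLR2 = 1, TLR4 = 1, XRCC1 = 1)
}

default_control_counts <- function() {
  c(PMS2 = 4, NBN = 4, FH = 0, RET = 2,
    DMBT1 = 2, RAD50 = 3, ATRIP = 3, BLM = 7, ERCC2 = 8, LIG3 = 1, MSH3 = 6,
    SLX4 = 2, AXIN1 = 0, ERCC5 = 0, ERCC6 = 0, EXO1 = 2, FANCA = 7,
    FANCD2 = 0, FANCG = 2, HOXB13 = 4, MCPH1 = 10, MDC1 = 0, MLH3 = 1,
    MMP8 = 5, NHEJ1 = 0, PIK3CG = 0, PMS1 = 2, RAD1 = 0, RECQL5 = 6,
    SBDS = 13, SETX = 10, SMARCA4 = 0, TLR2 = 1, TLR4 = 2, XRCC1 = 7)
}

# Clinical covariate marginals of the reproduced HCC transplant-candidate
# cohort (correlations between covariates are not modelled).
default_covariate_params <- function() {
  list(p_male = 258 / 334,
       etiology_probs = c(alcoholic = 0.386, viral = 0.359,
                          cholestatic_autoimmune = 0.144, NASH = 0.087,
                          metabolic = 0.009, none = 0.015),
       p_diabetes = 0.413, p_obesity = 0.281, p_smoking = 0.575,
       p_family_history = 0.392, p_multiple_primary = 0.171,
       p_microangioinvasion = 0.456, p_cholangio_differentiation = 0.054,
       p_recurrence = 0.10,
       age_mean = 62.5, age_sd = 8, age_range = c(26, 77))
}

#' Simulation configuration for a synthetic case-control cohort
#'
#' Defines a two-group cohort (cases vs population controls) with known
#' ground truth: per-gene, per-group probabilities that a subject carries a
#' retainable pathogenic variant; expected per-subject counts of "nuisance"
#' variants constructed to be removed at a named cascade stage; exponential
#' survival with administrative censoring; and clinical covariate marginals.
#' Defaults mirror the reproduced HCC liver-transplant cohort: 334 cases,
#' 1662 controls, carrier probabilities from the published per-gene carrier
#' counts, covariate prevalences from the published cohort table.
#'
#' @param n_cases,n_controls Subject counts (non-negative integers).
#' @param carrier_prob_cases,carrier_prob_controls Named vectors, gene symbol
#'   to per-subject carrier probability; genes must be on `panel`.
#' @param nuisance_rate Named vector, removal-stage label (a
#'   [cascade_stages()] entry or `"final_not_pathogenic"`) to the expected
#'   number of such variants per subject (Poisson). Default 0.5 per stage.
#' @param survival_params List: `hazard` (baseline event hazard per month),
#'   `carrier_hazard_ratio` (hazard multiplier for carriers; 1 = the null of
#'   comparable survival), `horizon_months` (administrative censoring).
#' @param covariate_params List of covariate prevalences; see defaults.
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] output
#'   byte-identical.
#' @param panel A [gene_panel()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_cases = 334, n_controls = 1662,
                          carrier_prob_cases = default_case_counts() / 334,
                          carrier_prob_controls = default_control_counts() / 1662,
                          nuisance_rate = stats::setNames(
                            rep(0.5, length(removal_labels())),
                            removal_labels()),
                          survival_params = list(hazard = 0.006,
                                                 carrier_hazard_ratio = 1,
                                                 horizon_months = 240),
                          covariate_params = default_covariate_params(),
                          seed = 1L,
                          panel = default_gene_panel()) {
  if (!is_count(n_cases) || !is_count(n_controls)) {
    stop_cfg("n_cases and n_controls must be non-negative integers")
  }
  stopifnot(inherits(panel, "gene_panel"))
  probs <- list(carrier_prob_cases = carrier_prob_cases,
                carrier_prob_controls = carrier_prob_controls)
  for (nm in names(probs)) {
    p <- probs[[nm]]
    if (length(p) && (is.null(names(p)) || any(!nzchar(names(p))))) {
      stop_cfg("%s must be a named vector (gene -> probability)", nm)
    }
    if (!is_prob(p)) stop_cfg("%s values must be probabilities in [0, 1]", nm)
    unknown <- setdiff(names(p), names(panel$genes))
    if (length(unknown)) {
      stop_cfg("%s names gene(s) not in the panel: %s", nm,
               paste(unknown, collapse = ", "))
    }
  }
  if (length(nuisance_rate)) {
    unknown <- setdiff(names(nuisance_rate), removal_labels())
    if (length(unknown)) {
      stop_cfg("unknown nuisance stage label(s): %s",
               paste(unknown, collapse = ", "))
    }
    if (any(nuisance_rate < 0)) stop_cfg("nuisance rates must be >= 0")
  }
  if (!is.numeric(survival_params$hazard) || survival_params$hazard < 0 ||
      survival_params$horizon_months <= 0 ||
      survival_params$carrier_hazard_ratio <= 0) {
    stop_cfg("invalid survival parameters")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop_cfg("seed must be an integer")
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 carrier_prob_cases = carrier_prob_cases,
                 carrier_prob_controls = carrier_prob_controls,
                 nuisance_rate = nuisance_rate,
                 survival_params = survival_params,
                 covariate_params = covariate_params,
                 seed = as.integer(seed), panel = panel),
            class = "cohort_config")
}

# --- internal field builders (plain lists; validated in bulk on assembly) ---

variant_base_fields <- function(gene, sample_id, variant_id) {
  list(sample_id = sample_id, gene = gene, variant_id = variant_id,
       quality = round(stats::runif(1, 200, 999)), in_repeat_region = FALSE,
       consequence = "missense", intron_offset = 0L, in_last_exon = FALSE,
       maf_supercontrols = 0, maf_gnomad = 0, maf_1000g = NA_real_,
       maf_esp = NA_real_, maf_exac = NA_real_, clinvar = "none",
       known_sequencing_error = FALSE, known_pathogenic_whitelisted = FALSE)
}

carrier_fields <- function(gene, sample_id, variant_id) {
  v <- variant_base_fields(gene, sample_id, variant_id)
  arch <- sample(c("frameshift", "stop_gained", "canonical_splice",
                   "missense"), 1L)
  v$consequence <- arch
  if (arch == "canonical_splice") {
    v$intron_offset <- sample(c(-2L, -1L, 1L, 2L), 1L)
  }
  v$clinvar <- if (arch == "missense") {
    sample(c("pathogenic", "likely_pathogenic"), 1L)
  } else {
    sample(c("pathogenic", "likely_pathogenic", "none"), 1L)
  }
  v$maf_supercontrols <- sample(c(NA_real_, 0, 0.001), 1L)
  v$maf_gnomad <- sample(c(NA_real_, 0, 0.0005), 1L)
  v
}

nuisance_fields <- function(stage_label, gene, sample_id, variant_id) {
  v <- variant_base_fields(gene, sample_id, variant_id)
  switch(stage_label,
    i_quality = { v$quality <- round(stats::runif(1, 0, 149)) },
    ii_repeat = { v$in_repeat_region <- TRUE },
    iii_noncoding_inframe = {
      v$consequence <- sample(c("utr", "upstream_downstream_intergenic",
                                "inframe_indel"), 1L)
    },
    iv_supercontrol_maf = {
      v$maf_supercontrols <- stats::runif(1, 0.005, 0.05)
      v$consequence <- "frameshift"  # would otherwise be retained
    },
    v_population_maf = {
      v$maf_gnomad <- stats::runif(1, 0.005, 0.05)
      v$consequence <- "frameshift"
    },
    vi_clinvar_benign = {
      v$clinvar <- sample(c("benign", "likely_benign"), 1L)
    },
    vii_last_exon = {
      v$in_last_exon <- TRUE
      v$consequence <- "stop_gained"
    },
    viii_deep_intronic = {
      v$consequence <- "intronic"
      v$intron_offset <- sample(c(-1L, 1L), 1L) * sample(3:50, 1L)
    },
    ix_synonymous = { v$consequence <- "synonymous" },
    x_sequencing_error = {
      v$known_sequencing_error <- TRUE
      v$consequence <- "frameshift"
    },
    final_not_pathogenic = {
      v$clinvar <- sample(c("vus", "conflicting", "none"), 1L)
    })
  v
}

assemble_variants <- function(rows) {
  if (!length(rows)) return(annotated_variants(empty_variant_frame()))
  reg <- variant_columns()
  cols <- lapply(stats::setNames(nm = names(reg)), function(col) {
    proto <- switch(reg[[col]], character = NA_character_,
                    numeric = NA_real_, integer = NA_integer_, logical = NA)
    vapply(rows, function(r) {
      x <- r[[col]]
      if (is.null(x)) proto else x
    }, proto)
  })
  annotated_variants(as.data.frame(cols, stringsAsFactors = FALSE))
}

empty_variant_frame <- function() {
  reg <- variant_columns()
  cols <- lapply(reg, function(ty) vector(
    switch(ty, character = "character", numeric = "numeric",
           integer = "integer", logical = "logical"), 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Construct a variant guaranteed to survive the cascade
#'
#' Draws one of the retention archetypes — frameshift, stop-gain, canonical
#' splice-site (+/-1-2 bp), or a ClinVar-pathogenic missense (testing the
#' ClinVar route rather than the truncation route) — with clean annotations:
#' high quality, non-repeat, all MAFs at or below the cutoff, no error flags.
#' Uses the current RNG stream.
#'
#' @param gene Gene symbol.
#' @param sample_id,variant_id Identifiers to stamp on the record.
#' @return One-row [annotated_variants()] table.
#' @export
make_carrier_variant <- function(gene, sample_id = "S1",
                                 variant_id = paste0(gene, ":pv1")) {
  assemble_variants(list(carrier_fields(gene, sample_id, variant_id)))
}

#' Construct a variant removed at a named cascade stage
#'
#' Returns a variant that fails exactly the pass-predicate of `stage_label`
#' while passing every earlier stage, so the cascade's first-failure
#' attribution must assign it to that stage. The base record is an otherwise
#' clean coding variant. Uses the current RNG stream.
#'
#' @param stage_label One of [cascade_stages()] or `"final_not_pathogenic"`.
#' @inheritParams make_carrier_variant
#' @return One-row [annotated_variants()] table.
#' @export
make_nuisance_variant <- function(stage_label, gene, sample_id = "S1",
                                  variant_id = paste0(gene, ":nv1")) {
  if (length(stage_label) != 1L || !stage_label %in% removal_labels()) {
    stop_cfg("unknown cascade stage: %s",
             paste(as.character(stage_label), collapse = ", "))
  }
  assemble_variants(list(nuisance_fields(stage_label, gene, sample_id,
                                         variant_id)))
}

#' Simulate an annotated case-control cohort with ground truth
#'
#' Generates, deterministically under `config$seed`: (1) an annotated variant
#' table containing planted carrier variants (Bernoulli per subject, gene and
#' group) plus Poisson-distributed nuisance variants targeted at named
#' cascade stages; (2) a phenotype table with one row per subject (group,
#' demographics, etiology, tumor features, exponential survival censored at
#' the horizon, and per-class carrier flags implied by the planted variants);
#' and (3) the ground truth indexing every planted carrier and the intended
#' removal stage of every nuisance variant.
#'
#' @param config A [cohort_config()].
#' @return List of class `simulated_cohort` with elements `variants`
#'   ([annotated_variants()]), `phenotypes` (data.frame) and `truth` (list
#'   with data.frames `planted` and `nuisance`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  ids <- c(sprintf("HCC%05d", seq_len(config$n_cases)),
           sprintf("PMC%05d", seq_len(config$n_controls)))
  group <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

  counter <- 0L
  rows <- list()
  planted <- list()
  nuisance <- list()

  # planted carriers: Bernoulli per subject x gene, independently per group
  plant <- function(sub_ids, probs) {
    if (!length(probs) || !length(sub_ids)) return()
    u <- matrix(stats::runif(length(sub_ids) * length(probs)),
                nrow = length(sub_ids))
    thresh <- matrix(probs, nrow = length(sub_ids), ncol = length(probs),
                     byrow = TRUE)
    hits <- which(u < thresh, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(hits))) {
      id <- sub_ids[hits[r, 1L]]
      g <- names(probs)[hits[r, 2L]]
      counter <<- counter + 1L
      vid <- sprintf("%s:sim%06d", g, counter)
      rows[[length(rows) + 1L]] <<- carrier_fields(g, id, vid)
      planted[[length(planted) + 1L]] <<- c(id, g, vid)
    }
  }
  plant(ids[group == "case"], config$carrier_prob_cases)
  plant(ids[group == "control"], config$carrier_prob_controls)

  # nuisance variants: Poisson per subject and stage
  panel_genes <- names(config$panel$genes)
  for (stage in names(config$nuisance_rate)) {
    k <- stats::rpois(length(ids), config$nuisance_rate[[stage]])
    for (i in which(k > 0)) {
      genes <- sample(panel_genes, k[i], replace = TRUE)
      for (g in genes) {
        counter <- counter + 1L
        vid <- sprintf("%s:sim%06d", g, counter)
        rows[[length(rows) + 1L]] <- nuisance_fields(stage, g, ids[i], vid)
        nuisance[[length(nuisance) + 1L]] <- c(vid, stage)
      }
    }
  }

  planted_df <- if (length(planted)) {
    m <- do.call(rbind, planted)
    data.frame(sample_id = m[, 1L], gene = m[, 2L], variant_id = m[, 3L],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(), gene = character(),
               variant_id = character(), stringsAsFactors = FALSE)
  }
  nuisance_df <- if (length(nuisance)) {
    m <- do.call(rbind, nuisance)
    data.frame(variant_id = m[, 1L], stage = m[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(), stage = character(),
               stringsAsFactors = FALSE)
  }

  structure(list(variants = assemble_variants(rows),
                 phenotypes = simulate_phenotypes(ids, group, planted_df,
                                                  config),
                 truth = list(planted = planted_df, nuisance = nuisance_df)),
            class = "simulated_cohort")
}

simulate_phenotypes <- function(ids, group, planted, config) {
  cp <- config$covariate_params
  sp <- config$survival_params
  n <- length(ids)
  panel <- config$panel

  carrier_genes <- split(planted$gene, planted$sample_id)
  flag_for <- function(genes_wanted) {
    vapply(ids, function(id) {
      g <- carrier_genes[[id]]
      !is.null(g) && any(g %in% genes_wanted)
    }, logical(1), USE.NAMES = FALSE)
  }
  est_genes <- names(panel$genes)[panel$genes == "established"]
  cand_genes <- names(panel$genes)[panel$genes == "candidate"]
  mrn_genes <- if ("MRN" %in% names(panel$gene_sets)) {
    panel$gene_sets$MRN
  } else character()

  etiology <- sample(names(cp$etiology_probs), n, replace = TRUE,
                     prob = cp$etiology_probs)
  age <- round(pmin(pmax(stats::rnorm(n, cp$age_mean, cp$age_sd),
                         cp$age_range[1]), cp$age_range[2]))
  carrier_any <- flag_for(names(panel$genes))
  hazard <- sp$hazard * ifelse(carrier_any, sp$carrier_hazard_ratio, 1)
  true_time <- stats::rexp(n, rate = pmax(hazard, 1e-12))
  event <- true_time <= sp$horizon_months
  time <- pmin(true_time, sp$horizon_months)

  data.frame(
    sample_id = ids, group = group,
    carrier_established = flag_for(est_genes),
    carrier_candidate = flag_for(cand_genes),
    carrier_MRN = flag_for(mrn_genes),
    carrier_any = carrier_any,
    age_at_dx = age,
    sex = ifelse(stats::runif(n) < cp$p_male, "M", "F"),
    etiology = etiology,
    cirrhosis = etiology != "none",
    diabetes = stats::runif(n) < cp$p_diabetes,
    obesity = stats::runif(n) < cp$p_obesity,
    smoking = stats::runif(n) < cp$p_smoking,
    microangioinvasion = stats::runif(n) < cp$p_microangioinvasion,
    cholangio_differentiation = stats::runif(n) < cp$p_cholangio_differentiation,
    recurrence = stats::runif(n) < cp$p_recurrence,
    multiple_primary = stats::runif(n) < cp$p_multiple_primary,
    family_history = stats::runif(n) < cp$p_family_history,
    survival_months = time, event = event,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(paste0("Simulated cohort: %d subject(s), %d variant record(s) ",
                     "(%d planted carrier, %d nuisance)\n"),
              nrow(x$phenotypes), nrow(x$variants), nrow(x$truth$planted),
              nrow(x$truth$nuisance)))
  invisible(x)
}
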