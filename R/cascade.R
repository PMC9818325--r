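#' Prioritization cascade configuration
#'
#' Tunable thresholds of the variant prioritization cascade.
#'
#' @param quality_min Minimum caller quality score (opaque caller units); a
#'   variant with `quality < quality_min` is removed at the quality stage.
#'   Default 150.
#' @param maf_max Maximum minor allele frequency, as a fraction; variants with
#'   MAF strictly above this in super-controls or any population database are
#'   removed. Default 0.004 (0.4%).
#' @param splice_window_bp Distance from an exon boundary (bp) within which an
#'   intronic position still counts as a conserved splice site. Default 2.
#' @return Object of class `prioritization_config`.
#' @export
prioritization_config <- function(quality_min = 150, maf_max = 0.004,
                                  splice_window_bp = 2L) {
  if (!is.numeric(quality_min) || length(quality_min) != 1L || quality_min < 0)
    stop_cfg("quality_min must be a single non-negative number")
  if (!is.numeric(maf_max) || length(maf_max) != 1L || maf_max <= 0 || maf_max >= 1)
    stop_cfg("maf_max must be in (0, 1)")
  if (!is_count(splice_window_bp) || splice_window_bp < 1)
    stop_cfg("splice_window_bp must be a positive integer")
  structure(list(quality_min = quality_min, maf_max = maf_max,
                 splice_window_bp = as.integer(splice_window_bp)),
            class = "prioritization_config")
}

#' Cascade stage labels, in order of application
#'
#' The ten sequential removal stages: (i) low caller quality; (ii) repetitive /
#' low-complexity regions; (iii) non-coding (UTR, upstream/downstream/
#' intergenic) and in-frame indels; (iv) super-control MAF above the cutoff;
#' (v) population-database MAF above the cutoff in any of gnomAD, 1000 Genomes,
#' ESP, ExAC; (vi) ClinVar benign/likely benign; (vii) last-exon location;
#' (viii) deep-intronic (beyond the splice window); (ix) synonymous;
#' (x) known recurrent sequencing errors unless whitelisted as known
#' pathogenic. Survivors are then retained only if ClinVar
#' pathogenic/likely-pathogenic or protein-truncating (stop-gain, frameshift,
#' splice within the window, or a copy-number deletion); otherwise they are
#' removed with the pseudo-stage `final_not_pathogenic`.
#'
#' @return Character vector of the ten stage labels.
#' @export
cascade_stages <- function() {
  c("i_quality", "ii_repeat", "iii_noncoding_inframe", "iv_supercontrol_maf",
    "v_population_maf", "vi_clinvar_benign", "vii_last_exon",
    "viii_deep_intronic", "ix_synonymous", "x_sequencing_error")
}

# all removal labels a FilterOutcome may carry
removal_labels <- function() c(cascade_stages(), "final_not_pathogenic")

# CNV calls have no exon geometry: exempt from the stages whose predicates are
# defined by exon coordinates (iii, vii, viii, ix). Frequency, quality, repeat,
# ClinVar and error-blacklist stages still apply.
is_cnv <- function(consequence) {
  consequence %in% c("cnv_deletion", "cnv_duplication")
}

#' Evaluate one cascade stage predicate
#'
#' Pure predicate: does each variant pass (survive) the named stage?
#' Vectorised over the rows of `variants`.
#'
#' @param variants An [annotated_variants()] table (or coercible data.frame).
#' @param stage One of [cascade_stages()].
#' @param config A [prioritization_config()].
#' @return Logical vector, `TRUE` where the variant passes the stage.
#' @export
passes_stage <- function(variants, stage, config = prioritization_config()) {
  if (!inherits(variants, "annotated_variants")) {
    variants <- annotated_variants(variants)
  }
  stopifnot(inherits(config, "prioritization_config"))
  if (length(stage) != 1L || !stage %in% cascade_stages()) {
    stop_cfg("unknown cascade stage: %s",
             paste(as.character(stage), collapse = ", "))
  }
  v <- variants
  cnv <- is_cnv(v$consequence)
  w <- config$splice_window_bp
  switch(stage,
    i_quality = v$quality >= config$quality_min,
    ii_repeat = !v$in_repeat_region,
    iii_noncoding_inframe = cnv |
      !(v$consequence %in% c("utr", "upstream_downstream_intergenic",
                             "inframe_indel")),
    iv_supercontrol_maf = is.na(v$maf_supercontrols) |
      v$maf_supercontrols <= config$maf_max,
    v_population_maf = {
      over <- rep(FALSE, nrow(v))
      for (col in maf_population_columns()) {
        over <- over | (!is.na(v[[col]]) & v[[col]] > config$maf_max)
      }
      !over
    },
    vi_clinvar_benign = !(v$clinvar %in% c("benign", "likely_benign")),
    vii_last_exon = cnv | !v$in_last_exon,
    viii_deep_intronic = cnv |
      !(v$consequence == "intronic" & abs(v$intron_offset) > w),
    ix_synonymous = cnv | v$consequence != "synonymous",
    x_sequencing_error = !(v$known_sequencing_error &
                             !v$known_pathogenic_whitelisted)
  )
}

# Final retention rule applied to survivors of stages i..x: keep if ClinVar
# P/LP, or protein-truncating (stop-gain / frameshift / CNV deletion), or at a
# conserved splice position (canonical_splice, or intronic within the window).
retention_rule <- function(variants, config) {
  w <- config$splice_window_bp
  clinvar_route <- variants$clinvar %in% c("pathogenic", "likely_pathogenic")
  truncating <- variants$consequence %in% c("stop_gained", "frameshift",
                                            "cnv_deletion")
  splice <- (variants$consequence %in% c("canonical_splice", "intronic")) &
    abs(variants$intron_offset) <= w & variants$intron_offset != 0L
  clinvar_route | truncating | splice
}

#' Apply the full prioritization cascade
#'
#' Runs every variant through the ten sequential stages and the final
#' retention rule, recording for each variant either `retained` or the first
#' stage at which it was removed. Stage order affects only this attribution:
#' the retained set equals the set passing the conjunction of all predicates.
#'
#' @inheritParams passes_stage
#' @return A data.frame of class `filter_outcomes`: the input columns plus
#'   `status` (`"retained"`/`"removed"`), `removal_stage` (a stage label,
#'   `"final_not_pathogenic"`, or `NA` for retained variants) and
#'   `stage_detail` (human-readable reason). Input order is preserved.
#' @export
apply_filter_cascade <- function(variants, config = prioritization_config()) {
  if (!inherits(variants, "annotated_variants")) {
    variants <- annotated_variants(variants)
  }
  stopifnot(inherits(config, "prioritization_config"))
  n <- nrow(variants)
  removal_stage <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  for (stage in cascade_stages()) {
    fails <- alive & !passes_stage(variants, stage, config)
    removal_stage[fails] <- stage
    alive <- alive & !fails
  }
  final_fail <- alive & !retention_rule(variants, config)
  removal_stage[final_fail] <- "final_not_pathogenic"
  alive <- alive & !final_fail

  detail <- stage_detail_text(variants, removal_stage, config)
  out <- variants
  out$status <- ifelse(alive, "retained", "removed")
  out$removal_stage <- removal_stage
  out$stage_detail <- detail
  class(out) <- c("filter_outcomes", "data.frame")
  out
}

stage_detail_text <- function(v, stage, config) {
  txt <- rep(NA_character_, nrow(v))
  set <- function(lab, msg) {
    i <- which(!is.na(stage) & stage == lab)
    if (length(i)) txt[i] <<- msg[if (length(msg) == 1L) rep(1L, length(i)) else i]
    invisible(NULL)
  }
  set("i_quality", sprintf("quality below %s", format(config$quality_min)))
  set("ii_repeat", "repetitive/low-complexity region")
  set("iii_noncoding_inframe", "non-coding consequence or in-frame indel")
  set("iv_supercontrol_maf",
      sprintf("super-control MAF above %s", format(config$maf_max)))
  set("v_population_maf",
      sprintf("population MAF above %s", format(config$maf_max)))
  set("vi_clinvar_benign", "ClinVar benign/likely benign")
  set("vii_last_exon", "located in last exon")
  set("viii_deep_intronic",
      sprintf("intronic beyond %d bp of exon boundary", config$splice_window_bp))
  set("ix_synonymous", "synonymous")
  set("x_sequencing_error", "known sequencing error, not whitelisted")
  set("final_not_pathogenic",
      "neither ClinVar pathogenic/likely pathogenic nor truncating/splice")
  txt
}

#' @export
print.filter_outcomes <- function(x, ...) {
  cat(sprintf("Filter outcomes: %d variant(s), %d retained, %d removed\n",
              nrow(x), sum(x$status == "retained"), sum(x$status == "removed")))
  invisible(x)
}

#' Retained variants of a cascade run
#'
#' @param outcomes A `filter_outcomes` table from [apply_filter_cascade()].
#' @return An [annotated_variants()] table of the retained records.
#' @export
retained_variants <- function(outcomes) {
  stopifnot(inherits(outcomes, "filter_outcomes"))
  keep <- outcomes[outcomes$status == "retained",
                   names(variant_columns()), drop = FALSE]
  rownames(keep) <- NULL
  annotated_variants(keep)
}

#' Per-stage removal counts
#'
#' Audit table over a cascade run: number of variants removed at each stage
#' (including the final retention rule) plus the retained count.
#'
#' @param outcomes A `filter_outcomes` table from [apply_filter_cascade()].
#' @return data.frame with columns `stage` and `removed`; attribute
#'   `retained` carries the retained count.
#' @export
audit_summary <- function(outcomes) {
  stopifnot(inherits(outcomes, "filter_outcomes"))
  labs <- removal_labels()
  removed <- vapply(labs, function(s) {
    sum(!is.na(outcomes$removal_stage) & outcomes$removal_stage == s)
  }, integer(1))
  out <- data.frame(stage = labs, removed = unname(removed),
                    stringsAsFactors = FALSE)
  attr(out, "retained") <- sum(outcomes$status == "retained")
  out
}
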