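#' Controlled vocabularies for annotated variants
#'
#' Functional consequence classes and ClinVar interpretation levels accepted in
#' a variant table. Consequences cover the annotation granularity the
#' prioritization cascade actually consumes: protein-truncating classes
#' (`frameshift`, `stop_gained`), splice-region (`canonical_splice`), other
#' coding classes (`missense`, `synonymous`, `inframe_indel`), non-coding
#' classes (`utr`, `upstream_downstream_intergenic`, `intronic`) and copy-number
#' calls (`cnv_deletion`, `cnv_duplication`).
#'
#' @return Character vector of allowed values.
#' @export
consequence_levels <- function() {
  c("frameshift", "stop_gained", "canonical_splice", "missense", "synonymous",
    "inframe_indel", "utr", "upstream_downstream_intergenic", "intronic",
    "cnv_deletion", "cnv_duplication")
}

#' @rdname consequence_levels
#' @export
clinvar_levels <- function() {
  c("pathogenic", "likely_pathogenic", "vus", "benign", "likely_benign",
    "conflicting", "none")
}

# Population frequency databases screened at the population-MAF stage.
maf_population_columns <- function() {
  c("maf_gnomad", "maf_1000g", "maf_esp", "maf_exac")
}

#' Column registry of the annotated variant table
#'
#' The canonical tab-separated interchange schema: one row per called variant
#' per sample, holding exactly the annotation fields the prioritization cascade
#' reads. Population MAFs (gnomAD, 1000 Genomes, ESP, ExAC) and the
#' super-control MAF may be `NA` when a variant is absent from the database.
#'
#' @return Named character vector mapping column name to storage type
#'   (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @export
variant_columns <- function() {
  c(sample_id = "character",
    gene = "character",
    variant_id = "character",
    quality = "numeric",
    in_repeat_region = "logical",
    consequence = "character",
    intron_offset = "integer",
    in_last_exon = "logical",
    maf_supercontrols = "numeric",
    maf_gnomad = "numeric",
    maf_1000g = "numeric",
    maf_esp = "numeric",
    maf_exac = "numeric",
    clinvar = "character",
    known_sequencing_error = "logical",
    known_pathogenic_whitelisted = "logical")
}

#' Build and validate an annotated variant table
#'
#' Coerces a data.frame to the canonical variant schema (see
#' [variant_columns()]) and enforces the field invariants: non-empty
#' identifiers, non-negative quality, MAFs in \[0, 1\], consequences and ClinVar
#' interpretations from the controlled vocabularies, and a non-zero
#' `intron_offset` only for `intronic`/`canonical_splice` records.
#'
#' @param df A data.frame with at least the columns of [variant_columns()].
#'   Missing MAF columns are added as `NA`; missing flag columns default to
#'   `FALSE`; a missing `intron_offset` defaults to 0.
#' @return The validated data.frame, columns ordered per the registry, with
#'   class `annotated_variants` prepended.
#' @export
annotated_variants <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  optional_defaults <- list(
    intron_offset = 0L, in_last_exon = FALSE, in_repeat_region = FALSE,
    maf_supercontrols = NA_real_, maf_gnomad = NA_real_, maf_1000g = NA_real_,
    maf_esp = NA_real_, maf_exac = NA_real_, clinvar = "none",
    known_sequencing_error = FALSE, known_pathogenic_whitelisted = FALSE)
  for (col in names(optional_defaults)) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(optional_defaults[[col]], nrow(df))
    }
  }
  reg <- variant_columns()
  missing <- setdiff(names(reg), names(df))
  if (length(missing)) {
    stop_cfg("variant table is missing mandatory column(s): %s",
             paste(missing, collapse = ", "))
  }
  df <- df[names(reg)]
  for (col in names(reg)) {
    df[[col]] <- switch(reg[[col]],
      character = as.character(df[[col]]),
      numeric = as.numeric(df[[col]]),
      integer = as.integer(df[[col]]),
      logical = as.logical(df[[col]]))
  }
  validate_variants(df)
  class(df) <- c("annotated_variants", "data.frame")
  df
}

validate_variants <- function(df) {
  bad_row <- function(ok, what) {
    if (!all(ok)) {
      stop_cfg("invalid %s in variant table row(s): %s", what,
               paste(utils::head(which(!ok), 5L), collapse = ", "))
    }
  }
  n <- nrow(df)
  if (n == 0L) return(invisible(df))
  bad_row(!is.na(df$sample_id) & nzchar(df$sample_id), "sample_id")
  bad_row(!is.na(df$gene) & nzchar(df$gene), "gene")
  bad_row(!is.na(df$variant_id) & nzchar(df$variant_id), "variant_id")
  bad_row(!is.na(df$quality) & df$quality >= 0, "quality")
  bad_row(df$consequence %in% consequence_levels(), "consequence")
  bad_row(df$clinvar %in% clinvar_levels(), "clinvar interpretation")
  for (col in c("maf_supercontrols", maf_population_columns())) {
    v <- df[[col]]
    bad_row(is.na(v) | (v >= 0 & v <= 1), col)
  }
  for (col in c("in_repeat_region", "in_last_exon", "known_sequencing_error",
                "known_pathogenic_whitelisted")) {
    bad_row(!is.na(df[[col]]), col)
  }
  off_ok <- !is.na(df$intron_offset) &
    (df$intron_offset == 0L |
       df$consequence %in% c("intronic", "canonical_splice"))
  bad_row(off_ok, "intron_offset (non-zero only for intronic/splice records)")
  invisible(df)
}

#' @export
print.annotated_variants <- function(x, ...) {
  cat(sprintf("Annotated variant table: %d record(s), %d sample(s), %d gene(s)\n",
              nrow(x), length(unique(x$sample_id)), length(unique(x$gene))))
  NextMethod()
}
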