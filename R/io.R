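# INFO keys of the minimal VCF dialect, mapped 1:1 to variant table columns.
vcf_info_map <- function() {
  c(SAMPLE = "sample_id", GENE = "gene", CSQ_CLASS = "consequence",
    INTRON_OFFSET = "intron_offset", LASTEX = "in_last_exon",
    REPEAT = "in_repeat_region", MAF_SC = "maf_supercontrols",
    MAF_GNOMAD = "maf_gnomad", MAF_1000G = "maf_1000g", MAF_ESP = "maf_esp",
    MAF_EXAC = "maf_exac", CLNSIG = "clinvar", SEQERR = "known_sequencing_error",
    KNOWN_PV = "known_pathogenic_whitelisted")
}

#' Read an annotated variant table
#'
#' Reads the canonical tab-separated variant table (columns per
#' [variant_columns()]) or the minimal VCF dialect written by
#' [write_variant_table()], whose INFO keys map 1:1 to the table columns
#' (SAMPLE, GENE, CSQ_CLASS, INTRON_OFFSET, LASTEX, REPEAT, MAF_SC,
#' MAF_GNOMAD, MAF_1000G, MAF_ESP, MAF_EXAC, CLNSIG, SEQERR, KNOWN_PV; caller
#' quality in the QUAL column, variant id in ID). Records are validated and
#' errors name the offending row.
#'
#' @param path Input file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return An [annotated_variants()] table.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_cfg("variant file not found: %s", path)
  if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
}

read_variant_tsv <- function(path) {
  reg <- variant_columns()
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  missing <- setdiff(names(reg), names(df))
  if (length(missing)) {
    stop_cfg("%s: missing mandatory column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  annotated_variants(df)
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(annotated_variants(empty_variant_frame()))
  info_map <- vcf_info_map()
  reg <- variant_columns()
  parse_info <- function(s) {
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    vals <- vapply(kv, function(p) if (length(p) > 1L) p[2] else "",
                   character(1))
    stats::setNames(vals, vapply(kv, `[[`, character(1), 1L))
  }
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    info <- parse_info(fix$INFO[i])
    missing <- setdiff(names(info_map), names(info))
    if (length(missing)) {
      stop_cfg("%s record %d: missing INFO key(s): %s", path, i,
               paste(missing, collapse = ", "))
    }
    out <- list(variant_id = fix$ID[i], quality = as.numeric(fix$QUAL[i]))
    for (key in names(info_map)) {
      col <- info_map[[key]]
      raw <- info[[key]]
      out[[col]] <- switch(reg[[col]],
        character = utils::URLdecode(raw),
        numeric = if (raw == ".") NA_real_ else as.numeric(raw),
        integer = as.integer(raw),
        logical = raw == "1")
    }
    out
  })
  assemble_variants(rows)
}

#' Write an annotated variant table
#'
#' Writes the canonical TSV (the lossless interchange format; round-trips
#' byte-identically through [read_variant_table()]) or the minimal VCF
#' dialect (synthetic CHROM/POS/REF/ALT placeholders, annotations in INFO).
#'
#' @param variants An [annotated_variants()] table (or coercible).
#' @param path Output file.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!inherits(variants, "annotated_variants")) {
    variants <- annotated_variants(variants)
  }
  if (dialect == "tsv") {
    utils::write.table(variants, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    write_variant_vcf(variants, path)
  }
  invisible(path)
}

write_variant_vcf <- function(variants, path) {
  info_map <- vcf_info_map()
  reg <- variant_columns()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cpgcascade",
    vapply(names(info_map), function(key) {
      col <- info_map[[key]]
      ty <- switch(reg[[col]], character = "String", numeric = "Float",
                   integer = "Integer", logical = "Integer")
      sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
              key, ty, col)
    }, character(1), USE.NAMES = FALSE),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt_val <- function(col, x) {
    switch(reg[[col]],
      character = utils::URLencode(x, reserved = TRUE),
      numeric = if (is.na(x)) "." else format(x, scientific = FALSE,
                                              trim = TRUE, digits = 15),
      integer = as.character(x),
      logical = if (x) "1" else "0")
  }
  body <- vapply(seq_len(nrow(variants)), function(i) {
    info <- paste(vapply(names(info_map), function(key) {
      col <- info_map[[key]]
      paste0(key, "=", fmt_val(col, variants[[col]][i]))
    }, character(1)), collapse = ";")
    paste("1", i, variants$variant_id[i], "N", "<ALT>",
          format(variants$quality[i], trim = TRUE), "PASS", info,
          sep = "\t")
  }, character(1))
  writeLines(c(header, body), path)
}

#' Read or write a phenotype table
#'
#' Tab-separated, one row per subject, columns as produced by
#' [simulate_cohort()]: identifiers, group, carrier flags, demographics,
#' etiology, tumor features, survival time (months) and event indicator.
#'
#' @param path File path.
#' @return `read_phenotype_table()` returns a data.frame.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop_cfg("phenotype file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  mandatory <- c("sample_id", "group")
  missing <- setdiff(mandatory, names(df))
  if (length(missing)) {
    stop_cfg("%s: missing mandatory column(s): %s", path,
             paste(missing, collapse = ", "))
  }
  bad <- which(!df$group %in% c("case", "control"))
  if (length(bad)) {
    stop_cfg("%s: invalid group value at row(s) %s", path,
             paste(utils::head(bad, 5L), collapse = ", "))
  }
  if ("survival_months" %in% names(df) &&
      any(df$survival_months < 0, na.rm = TRUE)) {
    stop_cfg("%s: negative survival_months", path)
  }
  df
}

#' @rdname read_phenotype_table
#' @param pheno Phenotype data.frame.
#' @export
write_phenotype_table <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Bundled example data: retained variants and control carrier counts
#'
#' `example_retained_variants()` returns the 48 retained pathogenic variants
#' of the reproduced 334-patient HCC cohort (per-sample rows; one patient
#' carries both a RAD50 and an ATRIP variant), encoded in the canonical
#' variant schema. Gene, variant id, consequence class and the
#' ClinVar-vs-truncation retention route follow the publication; caller
#' quality, MAF and flag fields are synthetic placeholders consistent with
#' retention. `example_control_counts()` returns the published per-gene
#' distinct-carrier counts among the 1662 population-matched controls.
#'
#' @return An [annotated_variants()] table, or a named integer vector.
#' @export
example_retained_variants <- function() {
  read_variant_table(system.file("extdata", "hcc334_retained_variants.tsv",
                                 package = "cpgcascade", mustWork = TRUE))
}

#' @rdname example_retained_variants
#' @export
example_control_counts <- function() {
  df <- utils::read.delim(system.file("extdata", "pmc1662_carrier_counts.tsv",
                                      package = "cpgcascade", mustWork = TRUE),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$carriers), df$gene)
}
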