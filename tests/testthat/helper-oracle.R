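# Independent oracles and generators used across test files.

# A clean coding variant that survives the whole cascade.
clean_variant <- function(sample_id = "S1", gene = "NBN",
                          variant_id = "NBN:test", consequence = "frameshift",
                          ...) {
  base <- list(sample_id = sample_id, gene = gene, variant_id = variant_id,
               quality = 500, in_repeat_region = FALSE,
               consequence = consequence, intron_offset = 0L,
               in_last_exon = FALSE, maf_supercontrols = 0.001,
               maf_gnomad = 0, maf_1000g = NA_real_, maf_esp = NA_real_,
               maf_exac = NA_real_, clinvar = "none",
               known_sequencing_error = FALSE,
               known_pathogenic_whitelisted = FALSE)
  mods <- list(...)
  base[names(mods)] <- mods
  annotated_variants(as.data.frame(base, stringsAsFactors = FALSE))
}

# Brute-force scalar re-derivation of the cascade: evaluates every predicate
# independently per variant and takes the first failure; membership equals the
# conjunction of all pass-predicates plus the retention rule. Written as plain
# first-principles if-chains, independent of the vectorised implementation.
oracle_outcome <- function(row, quality_min = 150, maf_max = 0.004,
                           splice_window = 2) {
  cnv <- row$consequence %in% c("cnv_deletion", "cnv_duplication")
  fails <- character()
  if (row$quality < quality_min) fails <- c(fails, "i_quality")
  if (row$in_repeat_region) fails <- c(fails, "ii_repeat")
  if (!cnv && row$consequence %in%
        c("utr", "upstream_downstream_intergenic", "inframe_indel")) {
    fails <- c(fails, "iii_noncoding_inframe")
  }
  if (!is.na(row$maf_supercontrols) && row$maf_supercontrols > maf_max) {
    fails <- c(fails, "iv_supercontrol_maf")
  }
  pop <- c(row$maf_gnomad, row$maf_1000g, row$maf_esp, row$maf_exac)
  if (any(!is.na(pop) & pop > maf_max)) fails <- c(fails, "v_population_maf")
  if (row$clinvar %in% c("benign", "likely_benign")) {
    fails <- c(fails, "vi_clinvar_benign")
  }
  if (!cnv && row$in_last_exon) fails <- c(fails, "vii_last_exon")
  if (!cnv && row$consequence == "intronic" &&
        abs(row$intron_offset) > splice_window) {
    fails <- c(fails, "viii_deep_intronic")
  }
  if (!cnv && row$consequence == "synonymous") fails <- c(fails, "ix_synonymous")
  if (row$known_sequencing_error && !row$known_pathogenic_whitelisted) {
    fails <- c(fails, "x_sequencing_error")
  }
  if (length(fails)) {
    return(list(status = "removed", stage = fails[1]))
  }
  pathogenic <- row$clinvar %in% c("pathogenic", "likely_pathogenic") ||
    row$consequence %in% c("stop_gained", "frameshift", "cnv_deletion") ||
    (row$consequence %in% c("canonical_splice", "intronic") &&
       row$intron_offset != 0 && abs(row$intron_offset) <= splice_window)
  if (pathogenic) list(status = "retained", stage = NA_character_)
  else list(status = "removed", stage = "final_not_pathogenic")
}

# Random variant batches biased towards boundary values of every predicate.
random_variants <- function(n) {
  pick <- function(vals) sample(vals, n, replace = TRUE)
  csq <- pick(consequence_levels())
  off <- ifelse(csq %in% c("intronic", "canonical_splice"),
                pick(c(-10L, -3L, -2L, -1L, 1L, 2L, 3L, 10L)), 0L)
  data.frame(
    sample_id = sprintf("S%03d", sample.int(50, n, replace = TRUE)),
    gene = pick(c("NBN", "RAD50", "MRE11", "FH", "DMBT1")),
    variant_id = sprintf("v%05d", seq_len(n)),
    quality = pick(c(0, 100, 149, 150, 151, 500, 999)),
    in_repeat_region = pick(c(TRUE, FALSE, FALSE, FALSE)),
    consequence = csq,
    intron_offset = off,
    in_last_exon = pick(c(TRUE, FALSE, FALSE, FALSE)),
    maf_supercontrols = pick(c(NA_real_, 0, 0.003, 0.004, 0.0041, 0.05)),
    maf_gnomad = pick(c(NA_real_, 0, 0.004, 0.0041, 0.1)),
    maf_1000g = pick(c(NA_real_, 0, 0.002, 0.02)),
    maf_esp = pick(c(NA_real_, 0, 0.005)),
    maf_exac = pick(c(NA_real_, 0, 0.004, 0.01)),
    clinvar = pick(clinvar_levels()),
    known_sequencing_error = pick(c(TRUE, FALSE, FALSE)),
    known_pathogenic_whitelisted = pick(c(TRUE, FALSE)),
    stringsAsFactors = FALSE)
}

# Random small 2x2 tables with all margins positive.
random_tables <- function(n, max_cell = 50) {
  replicate(n, {
    repeat {
      t <- sample.int(max_cell, 4, replace = TRUE)
      if (all(c(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4]) > 0)) {
        return(t)
      }
    }
  }, simplify = FALSE)
}

# Printed burden results of the reproduced study: per-gene distinct-carrier
# counts, odds ratio (1 decimal) and p-value at its printed precision
# (NA = printed "n.d.").
published_burden <- function() {
  read.delim(text = "gene	class	cases	controls	or	p	p_digits
PMS2	established	1	4	1.2	0.8	1
NBN	established	4	4	5.0	0.012	3
FH	established	1	0	NA	NA	NA
RET	established	1	2	2.5	0.4	1
DMBT1	candidate	3	2	7.5	0.010	3
RAD50	candidate	3	3	5.0	0.029	3
ATRIP	candidate	2	3	3.3	0.2	1
BLM	candidate	2	7	1.4	0.7	1
ERCC2	candidate	2	8	1.2	0.8	1
LIG3	candidate	2	1	10.0	0.021	3
MSH3	candidate	2	6	1.7	0.5	1
SLX4	candidate	2	2	5.0	0.1	1
AXIN1	candidate	1	0	NA	NA	NA
ERCC5	candidate	1	0	NA	NA	NA
ERCC6	candidate	1	0	NA	NA	NA
EXO1	candidate	1	2	2.5	0.4	1
FANCA	candidate	1	7	0.7	0.7	1
FANCD2	candidate	1	0	NA	NA	NA
FANCG	candidate	1	2	2.5	0.4	1
HOXB13	candidate	1	4	1.2	0.8	1
MCPH1	candidate	1	10	0.5	0.5	1
MDC1	candidate	1	0	NA	NA	NA
MLH3	candidate	1	1	5.0	0.2	1
MMP8	candidate	1	5	1.0	0.9	1
NHEJ1	candidate	1	0	NA	NA	NA
PIK3CG	candidate	1	0	NA	NA	NA
PMS1	candidate	1	2	2.5	0.4	1
RAD1	candidate	1	0	NA	NA	NA
RECQL5	candidate	1	6	0.8	0.9	1
SBDS	candidate	1	13	0.4	0.3	1
SETX	candidate	1	10	0.5	0.5	1
SMARCA4	candidate	1	0	NA	NA	NA
TLR2	candidate	1	1	5.0	0.2	1
TLR4	candidate	1	2	2.5	0.4	1
XRCC1	candidate	1	7	0.7	0.7	1",
             stringsAsFactors = FALSE)
}

fixture_carrier_matrices <- function(panel = default_gene_panel()) {
  cases <- classify_retained(apply_filter_cascade(example_retained_variants()),
                             panel)
  controls <- counts_to_carrier_matrix(example_control_counts(), panel)
  list(cases = cases, controls = controls)
}
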