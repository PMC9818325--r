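---
title: "Methods: variant prioritization, burden testing and cohort simulation"
author: "cpgcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant prioritization, burden testing and cohort simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgcascade)
```

## The problem this package addresses

Germline panel-NGS studies of cancer predisposition follow a common shape:
sequence a case cohort and population controls on a panel of
cancer-predisposition genes (CPGs), reduce tens of thousands of called
variants per cohort to a handful of clinically significant pathogenic
variants (PVs), count carriers, and ask whether any gene, gene class or gene
complex is enriched in cases. The archetype reproduced here is a cohort of
334 hepatocellular carcinoma (HCC) liver-transplant candidates screened on a
226-gene panel against 1662 population-matched controls, in which carriers
of variants in the MRN double-strand-break-repair complex (*MRE11*, *RAD50*,
*NBN*) stood out.

The scientific content of such a study lives almost entirely in annotations
and counts, not in raw reads. This package therefore begins *after*
alignment, calling and annotation: its inputs are annotated variant records
(gene, consequence class, caller quality, repeat flag, super-control and
population MAFs, ClinVar interpretation) plus a phenotype table, and its
outputs are the retained-variant list with a per-variant audit trail, the
carrier matrix, the burden table and the clinical comparison.

## The prioritization cascade

Variants are removed sequentially; each record keeps the **first** stage it
failed, which makes the audit table reproducible and additive. The stages,
with their exact predicates:

| stage | removes a variant iff |
|---|---|
| `i_quality` | caller quality < `quality_min` (default 150; quality exactly 150 passes) |
| `ii_repeat` | flagged in repetitive/low-complexity sequence |
| `iii_noncoding_inframe` | consequence is UTR, upstream/downstream/intergenic, or an in-frame indel |
| `iv_supercontrol_maf` | super-control MAF > `maf_max` (default 0.004; exactly 0.004 passes; absent = passes) |
| `v_population_maf` | **any** of gnomAD, 1000 Genomes, ESP, ExAC above `maf_max` |
| `vi_clinvar_benign` | ClinVar benign or likely benign |
| `vii_last_exon` | located in the last exon |
| `viii_deep_intronic` | intronic with \|offset\| > `splice_window_bp` (default 2) |
| `ix_synonymous` | synonymous |
| `x_sequencing_error` | on the recurrent-sequencing-error blacklist and not whitelisted as known pathogenic |

Survivors face the final retention rule: keep iff ClinVar
pathogenic/likely-pathogenic, **or** protein-truncating (stop-gain,
frameshift, copy-number deletion), **or** at a conserved splice position
(within ± `splice_window_bp` of an exon boundary). Everything else is removed
as `final_not_pathogenic`.

### Design choices in the cascade

Several points are genuinely open in this kind of protocol; the package's
choices, fixed once:

* **Boundary semantics.** "< 150" and "> 0.4%" are read strictly: quality
  150 and MAF 0.004 both pass. A MAF absent from a database is treated as 0
  (absence of evidence of commonness). The population-MAF stage removes on
  *any* database exceeding the cutoff — the most conservative aggregation.
* **Deep-intronic split.** Non-coding removal is split in two: stage iii
  covers UTR/upstream/downstream/intergenic and in-frame indels; intronic
  variants are judged at stage viii against the splice window. Intronic
  positions within the window are treated as canonical splice candidates and
  survive both stages; this keeps the two stages separately testable with no
  double attribution.
* **Whitelist scope.** The known-pathogenic whitelist exempts variants only
  from the sequencing-error stage (x), not from the geometry stages
  vii–ix. A last-exon ClinVar-pathogenic variant is therefore removed at
  stage vii — the narrowest reading of the exception; users who want a wider
  exemption can clear `in_last_exon` upstream.
* **Copy-number records.** CNV calls have no exon geometry, so they are
  exempt from stages iii, vii, viii and ix but subject to the frequency,
  quality, repeat, ClinVar and blacklist stages. `cnv_deletion` counts as
  truncating in the retention rule (multi-exon deletions are
  loss-of-function); `cnv_duplication` is retained only via the ClinVar
  route, since a duplication's effect is not predictable from the call alone.
* **Per-row processing.** Records are processed per (sample, variant); no
  cross-sample deduplication happens at this layer because carrier counting
  needs per-sample fates.

The suite asserts, against an independently written brute-force oracle, that
the retained set equals the conjunction of all pass-predicates plus the
retention rule (order affects attribution only), that the cascade is
idempotent on retained variants, and that tightening `maf_max` or
`quality_min` never grows the retained set.

## Carrier accounting and burden statistics

A *carrier* is a sample with at least one retained variant in a gene;
`classify_retained()` keeps distinct-sample sets per gene, per panel class
(established vs candidate CPGs) and per named gene set (default: MRN), so a
sample with variants in two genes appears in both genes' sets but once in
any union.

For *a* carriers among `n_cases` and *c* among `n_controls`
(b, d the complements):

* odds ratio: OR = a·d / (b·c), undefined when any cell is 0 (rendered
  "n.d.");
* 95% CI: Woolf's logit interval
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)), z = 1.959964;
* p-value: Pearson's chi-square n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)) on
  1 df, two-sided, **without** continuity correction. Fisher's exact test is
  available by flag, and an optional Bonferroni column can be emitted —
  the reproduced analysis applied no multiplicity correction, so none is
  applied by default.

Two numerical notes. First, the published cohort's interval bounds were
produced by a commercial package whose 2×2 CI method is a hybrid rather
than Woolf's closed form; the package's tests pin the Woolf bounds to the
published ones within 1% relative (three of the four highlighted lower
bounds agree exactly at two decimals). Woolf was chosen because it is
closed-form, standard and exactly reproducible. Second, report rendering
follows the published table's style: OR to 1 decimal, CI to 2 decimals,
and p to 3 decimals below 0.05, 1 decimal otherwise, half-up ("<0.001"
when 3 decimals would round to zero). Pearson without correction is the
only 2×2 test that reproduces the published p-values; recomputed values
agree with every printed p within the resolution of the printed digit
(most exactly; a few printed values sit one unit of the last digit away
from the recomputation, consistent with intermediate rounding in the
original report).

## Clinical comparison and survival

`compare_groups()` contrasts carriers vs non-carriers per characteristic:
chi-square (no continuity correction) for categorical and logical
characteristics, Mann-Whitney by default for continuous ones — a robust
choice for skewed clinical variables such as AFP — with Student's t
selectable and Kruskal-Wallis for multi-level groupings. A characteristic
constant in the pooled data or a comparison with an empty stratum is marked
*untestable* rather than failing the run, and the report records which test
was used where, since protocols of this kind rarely itemise that. No
multiplicity adjustment is applied.

Survival uses the Kaplan-Meier product-limit estimator and the log-rank
test via the `survival` package; censored subjects at a tied time remain at
risk for events at that time (the dominant convention). The tests verify
the estimator against hand-computed product-limit tables and the log-rank
p against a 10,000-draw permutation oracle.

## The synthetic cohort generator

`simulate_cohort()` exists so that every downstream stage has a testable
ground truth. Its defaults *are* the study conditions of the reproduced
cohort: 334 cases, 1662 controls, per-gene carrier probabilities equal to
the published per-gene carrier frequencies, and covariate marginals from
the published cohort table (77% male, 98.5% cirrhosis, etiology mix led by
alcoholic 38.6% and viral 35.9%, diabetes 41.3%, obesity 28.1%, smoking
57.5%, family history 39.2%; age ~ N(62.5, 8) truncated to 26–77).

* **Planted carriers** are Bernoulli per subject, gene and group; each
  planted record is drawn from the retention archetypes (frameshift,
  stop-gain, canonical splice ±1–2 bp, ClinVar-pathogenic missense) with
  clean annotations, so it must survive the cascade.
* **Nuisance variants** are Poisson per subject and stage; each is
  constructed to fail exactly its target stage while passing all earlier
  stages, so the cascade's first-failure attribution is fully determined.
  No public per-subject pre-filter variant counts exist for this protocol,
  so the default rate — 0.5 expected variants per subject per removal
  label — is an arbitrary but documented choice that exercises every stage
  without dominating runtime.
* **Survival** is exponential (default hazard 0.006/month, roughly the 70%
  five-year survival reported for liver-transplant recipients) with
  administrative censoring at 240 months and a carrier hazard ratio of 1 by
  default — the null of comparable survival, which is all the reproduced
  study's survival claim amounts to. Setting the ratio away from 1 turns
  the generator into a power harness for the log-rank machinery.

What the generator does **not** emulate: linkage and relatedness,
population structure, covariate correlations (only marginals are drawn),
genotype likelihoods, and sequence context (variants carry only the
annotation fields the cascade reads, since no stage consumes coordinates).
Passing tests on simulated cohorts therefore demonstrate the correctness of
the *pipeline logic* under the stated generative model, not robustness to
annotation errors or cohort artefacts in real data.

With a fixed seed the generator is byte-identical (the caller's RNG stream
is saved and restored), and the suite checks exact recovery: the retained
set equals the planted set, zero nuisance variants leak through, every
nuisance variant is attributed to its intended stage, and configured
carrier probabilities are recovered within exact binomial 95% intervals at
n = 10,000 across 20 seeds.

## Interfaces

The canonical interchange format is a fixed-schema TSV (one row per variant
per sample; `variant_columns()` documents the registry), which round-trips
byte-identically. A minimal VCF dialect is accepted and emitted as an
alternative, with annotation fields as INFO key-value pairs (`GENE`,
`CSQ_CLASS`, `MAF_SC`, `MAF_GNOMAD`, `CLNSIG`, `REPEAT`, `LASTEX`,
`INTRON_OFFSET`, `SEQERR`, `KNOWN_PV`, …) — the cascade consumes
annotations, not genomic records, so the TSV is primary. Gene panels are
YAML/JSON (`genes: {SYMBOL: established|candidate}`,
`gene_sets: {MRN: [...]}`); the bundled default panel carries every gene
symbol the reproduced study reports, extensible to the full 226.
`run_pipeline()` ties the stages together and writes the retained-variant
table, audit table, burden TSV/JSON and clinical JSON into a run directory;
being an R package, the exported functions and `scripts/acceptance.R` are
the command-line surface.

## Problem sizes and runtime

The test suite runs the full default-size cohort (1996 subjects, ~11,000
variant records) through the cascade, 1000-variant random batches against
the brute-force oracle, 200 null 2×2 tables plus 50 null log-rank cohorts
of 400 subjects for calibration, and 10,000-subject cohorts for frequency
recovery — about half a minute in total on one CPU. These sizes were chosen
to keep Monte-Carlo bands tight enough to be meaningful while keeping the
suite fast to iterate on.

## Known limitations

* The cascade reproduces one published protocol; it is not an ACMG
  classifier, and the sequencing-error blacklist is an input flag, not a
  computed artefact.
* The Woolf CI intentionally differs (within ~1%) from the hybrid method
  behind the published bounds; bounds, unlike ORs and p-values, are
  method-dependent.
* Carrier-level burden testing ignores covariates; regression-based burden
  tests (logistic, SKAT-type) are out of scope.
* Control carrier matrices built from published per-gene counts assume no
  control carries variants in two genes — exactly the convention of the
  published control counts, but an approximation for raw control data
  (where a control variant table should be supplied instead).
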