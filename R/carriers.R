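#' Distinct-sample carrier matrix
#'
#' Collapses retained variants to carrier sets: for each gene, each panel
#' class and each configured gene set, the set of distinct samples carrying at
#' least one retained pathogenic variant there. A sample with two retained
#' variants in one gene counts once for that gene; a sample with retained
#' variants in two genes appears in both genes' sets but once in any
#' class/set union.
#'
#' @param outcomes A `filter_outcomes` table from [apply_filter_cascade()], or
#'   an [annotated_variants()] table of already-retained variants.
#' @param panel A [gene_panel()]; every retained variant's gene must be on it.
#' @return Object of class `carrier_matrix`: list with `per_gene`, `per_class`
#'   and `per_set`, each a named list of character vectors of sample ids, plus
#'   `all` (distinct carriers overall).
#' @export
classify_retained <- function(outcomes, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  if (inherits(outcomes, "filter_outcomes")) {
    kept <- outcomes[outcomes$status == "retained", , drop = FALSE]
  } else {
    kept <- annotated_variants(outcomes)
  }
  unknown <- setdiff(unique(kept$gene), names(panel$genes))
  if (length(unknown)) {
    stop_cfg("retained variant gene(s) not in panel: %s",
             paste(sort(unknown), collapse = ", "))
  }
  per_gene <- lapply(stats::setNames(nm = names(panel$genes)), function(g) {
    sort(unique(kept$sample_id[kept$gene == g]))
  })
  classes <- c("established", "candidate")
  per_class <- lapply(stats::setNames(nm = classes), function(cl) {
    genes <- names(panel$genes)[panel$genes == cl]
    sort(unique(unlist(per_gene[genes], use.names = FALSE)))
  })
  per_set <- lapply(panel$gene_sets, function(members) {
    sort(unique(unlist(per_gene[members], use.names = FALSE)))
  })
  structure(list(per_gene = per_gene, per_class = per_class,
                 per_set = per_set,
                 all = sort(unique(kept$sample_id))),
            class = "carrier_matrix")
}

#' @export
print.carrier_matrix <- function(x, ...) {
  nonempty <- sum(lengths(x$per_gene) > 0)
  cat(sprintf(paste0("Carrier matrix: %d distinct carrier(s) overall; ",
                     "%d gene(s) with carriers (established: %d, candidate: %d)\n"),
              length(x$all), nonempty,
              length(x$per_class$established), length(x$per_class$candidate)))
  invisible(x)
}

#' Carrier matrix from per-gene carrier counts
#'
#' Builds a [classify_retained()]-compatible carrier matrix from per-gene
#' distinct-carrier counts (as published summary tables report for control
#' cohorts), materialising synthetic sample ids. Counts are assumed to refer
#' to disjoint samples across genes, so class/set unions equal column sums —
#' the convention of the published control counts.
#'
#' @param counts Named integer vector, gene symbol to distinct carrier count.
#' @param panel A [gene_panel()].
#' @param prefix Prefix for generated sample ids.
#' @return A `carrier_matrix`.
#' @export
counts_to_carrier_matrix <- function(counts, panel, prefix = "CTRL") {
  stopifnot(inherits(panel, "gene_panel"))
  unknown <- setdiff(names(counts), names(panel$genes))
  if (length(unknown)) {
    stop_cfg("carrier count gene(s) not in panel: %s",
             paste(unknown, collapse = ", "))
  }
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop_cfg("carrier counts must be non-negative integers")
  }
  rows <- list()
  next_id <- 1L
  for (g in names(counts)) {
    k <- counts[[g]]
    if (k > 0) {
      ids <- sprintf("%s%04d", prefix, seq.int(next_id, next_id + k - 1L))
      next_id <- next_id + k
      rows[[g]] <- data.frame(sample_id = ids, gene = g,
                              variant_id = paste0(g, ":count"),
                              stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(), gene = character(),
               variant_id = character(), stringsAsFactors = FALSE)
  }
  df$quality <- rep(999, nrow(df))
  df$consequence <- rep("frameshift", nrow(df))
  df$clinvar <- rep("pathogenic", nrow(df))
  classify_retained(annotated_variants(df), panel)
}

#' Number of distinct carriers for a label
#'
#' @param cm A `carrier_matrix`.
#' @param label A gene symbol, a class (`"established"`/`"candidate"`), a gene
#'   set name, or `"all"`.
#' @return Integer count of distinct carrier samples.
#' @export
carrier_count <- function(cm, label) {
  stopifnot(inherits(cm, "carrier_matrix"))
  ids <- carrier_ids(cm, label)
  length(ids)
}

carrier_ids <- function(cm, label) {
  if (label == "all") return(cm$all)
  if (label %in% names(cm$per_class)) return(cm$per_class[[label]])
  if (label %in% names(cm$per_set)) return(cm$per_set[[label]])
  if (label %in% names(cm$per_gene)) return(cm$per_gene[[label]])
  stop_cfg("unknown carrier label: %s", label)
}
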