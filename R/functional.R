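#' Build a taxon-to-KO functional mapping
#'
#' A user-supplied projection in the Tax4Fun spirit: non-negative weights
#' from taxa to KO3 pathways plus the KO3 -> KO2 -> KO1 hierarchy labels.
#'
#' @param weights non-negative matrix, taxa x KO3 pathways.
#' @param hierarchy data.frame with columns `ko3`, `ko2`, `ko1` covering
#'   every pathway column of `weights`.
#' @return Object of class `ko_mapping`.
#' @export
ko_mapping <- function(weights, hierarchy) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("mapping weights must be >= 0", call. = FALSE)
  if (!all(c("ko3", "ko2", "ko1") %in% colnames(hierarchy))) {
    stop("hierarchy needs columns ko3, ko2, ko1", call. = FALSE)
  }
  missing <- setdiff(colnames(weights), hierarchy$ko3)
  if (length(missing)) {
    stop("pathways without a KO1 ancestor: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(weights = weights, hierarchy = hierarchy),
            class = "ko_mapping")
}

#' Project taxon abundances onto KO pathways
#'
#' Pathway abundance is the matrix product of relative abundances and the
#' mapping weights over the shared taxa, renormalized per sample.
#' Coverage (fraction of table abundance that maps) is reported via a
#' message.
#'
#' @param rel_abund relative-abundance matrix, samples x taxa.
#' @param mapping a [ko_mapping()].
#' @return Matrix samples x pathways, rows summing to 1; attribute
#'   `coverage` holds the per-sample mapped fraction.
#' @export
project_ko <- function(rel_abund, mapping) {
  stopifnot(inherits(mapping, "ko_mapping"))
  rel_abund <- as.matrix(rel_abund)
  common <- intersect(colnames(rel_abund), rownames(mapping$weights))
  if (length(common) == 0) {
    stop("no taxa shared between table and mapping", call. = FALSE)
  }
  coverage <- rowSums(rel_abund[, common, drop = FALSE]) /
    rowSums(rel_abund)
  message(sprintf("project_ko: %d/%d taxa mapped (mean coverage %.1f%%)",
                  length(common), ncol(rel_abund), 100 * mean(coverage)))
  raw <- rel_abund[, common, drop = FALSE] %*%
    mapping$weights[common, , drop = FALSE]
  totals <- rowSums(raw)
  if (any(totals == 0)) {
    stop("sample(s) with zero projected abundance: ",
         paste(rownames(raw)[totals == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(raw, 1L, totals, "/")
  attr(out, "coverage") <- coverage
  attr(out, "unnormalized") <- raw
  out
}

#' Retain only Metabolism pathways
#'
#' Keeps KO3 pathways whose KO1 ancestor is "Metabolism"; reports the
#' number dropped.
#'
#' @param pathway_table samples x KO3 matrix from [project_ko()].
#' @param hierarchy data.frame with `ko3` and `ko1` columns.
#' @return Filtered matrix (possibly with zero columns, with a warning).
#' @export
filter_metabolism <- function(pathway_table, hierarchy) {
  keep_ko3 <- hierarchy$ko3[hierarchy$ko1 == "Metabolism"]
  keep <- colnames(pathway_table) %in% keep_ko3
  message(sprintf("filter_metabolism: dropped %d of %d pathways",
                  sum(!keep), ncol(pathway_table)))
  out <- pathway_table[, keep, drop = FALSE]
  if (ncol(out) == 0) {
    warning("no Metabolism pathways retained; empty table", call. = FALSE)
  }
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", "ns")))
}

#' Group-difference tests per pathway
#'
#' Applies [gate_and_compare()] to every pathway and assigns significance
#' stars at the conventional cutpoints (* p < 0.05, ** p < 0.01,
#' *** p < 0.001, ns above).
#'
#' @param pathway_table samples x pathways matrix.
#' @param groups group label per sample.
#' @return data.frame: `pathway`, `p`, `test_used`, `stars`, plus one
#'   letter column per group.
#' @export
differential_pathways <- function(pathway_table, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  rows <- lapply(colnames(pathway_table), function(pw) {
    cmp <- gate_and_compare(pathway_table[, pw], groups, trait = pw)
    out <- data.frame(pathway = pw, p = cmp$omnibus_p,
                      test_used = cmp$test_used,
                      stars = significance_stars(cmp$omnibus_p),
                      stringsAsFactors = FALSE)
    for (g in names(cmp$letters)) out[[paste0("letter_", g)]] <-
      cmp$letters[g]
    out
  })
  do.call(rbind, rows)
}
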