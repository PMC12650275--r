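#' Rarefy an ASV table to uniform depth
#'
#' Random subsampling of each sample's reads without replacement
#' (multivariate hypergeometric) to a common depth. Samples whose total is
#' below the target depth are dropped with a warning, never up-sampled.
#'
#' @param table an [asv_table()].
#' @param depth target depth; `NULL` uses the minimum sample total.
#' @param seed RNG seed for the subsampling.
#' @return A rarefied `asv_table`; every retained sample sums to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  stopifnot(inherits(table, "asv_table"))
  totals <- rowSums(table$counts)
  if (is.null(depth)) depth <- min(totals)
  if (depth <= 0) stop("rarefaction depth must be positive", call. = FALSE)
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), as.integer(depth),
                    paste(names(totals)[!keep], collapse = ", ")),
            call. = FALSE)
  }
  if (!any(keep)) stop("no sample reaches the rarefaction depth",
                       call. = FALSE)
  counts <- table$counts[keep, , drop = FALSE]
  # rrarefy's "observed counts" note is advisory and fires on any table
  # whose rarest retained ASV count exceeds 1; not informative here
  rare <- with_seed(seed, suppressWarnings(vegan::rrarefy(counts, depth)))
  storage.mode(rare) <- "integer"
  asv_table(rare, droplevels(table$groups[rownames(rare)]))
}

#' Per-sample relative abundances
#'
#' @param table an [asv_table()] or counts matrix (samples x ASVs).
#' @return Numeric matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  counts <- as_counts(table)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 1L, totals, "/")
}

#' Collapse an ASV table to a taxonomic rank
#'
#' Sums counts of ASVs sharing a lineage at `rank`; missing or NA
#' assignments pool into `"Unassigned"`. Per-sample totals are preserved
#' exactly.
#'
#' @param table an [asv_table()].
#' @param taxonomy data.frame of ranks (kingdom..species), rownames = ASV
#'   ids.
#' @param rank column of `taxonomy` to collapse to.
#' @return Matrix samples x taxa.
#' @export
aggregate_taxa <- function(table, taxonomy, rank) {
  stopifnot(inherits(table, "asv_table"))
  if (!rank %in% colnames(taxonomy)) {
    stop("unknown rank: ", rank, call. = FALSE)
  }
  lab <- as.character(taxonomy[asv_ids(table), rank])
  lab[is.na(lab) | lab == ""] <- "Unassigned"
  t(rowsum(t(table$counts), lab))
}

#' Group-level ASV partition report
#'
#' Pools counts within each group; an ASV is observed in a group iff its
#' pooled count is positive. Reports per-group observed totals, counts
#' unique to one group, the common-to-all core, and each group's share of
#' the summed totals (percent, 2 decimals) -- the arithmetic behind an
#' UpSet plot of pooled groups.
#'
#' @param table an [asv_table()] with at least two groups.
#' @return A list of class `partition_report`: `total`, `unique_to_group`,
#'   `common_to_all`, `share_pct` (all named by group), and the presence
#'   matrix.
#' @export
group_asv_partition <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  groups <- droplevels(table$groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  pooled <- rowsum(table$counts, groups)
  presence <- pooled > 0
  totals <- rowSums(presence)
  n_member <- colSums(presence)
  uniq <- sapply(levels(groups), function(g)
    sum(presence[g, ] & n_member == 1L))
  structure(list(
    total = totals,
    unique_to_group = uniq,
    common_to_all = sum(n_member == nlevels(groups)),
    share_pct = round(100 * totals / sum(totals), 2),
    presence = presence), class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat("ASV partition across groups\n")
  df <- data.frame(total = x$total, unique = x$unique_to_group,
                   share_pct = x$share_pct)
  print(df)
  cat("common to all groups:", x$common_to_all, "\n")
  invisible(x)
}

#' Alpha diversity (richness and Shannon index)
#'
#' Richness counts nonzero ASVs; Shannon is `-sum p log p` over nonzero
#' proportions, natural log by default.
#'
#' @param table an [asv_table()] or counts matrix.
#' @param base logarithm base for Shannon (default natural log).
#' @return data.frame with columns `sample`, `group` (if available),
#'   `richness`, `shannon`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  counts <- as_counts(table)
  richness <- rowSums(counts > 0)
  shannon <- vegan::diversity(counts, index = "shannon", base = base)
  out <- data.frame(sample = rownames(counts), richness = richness,
                    shannon = as.numeric(shannon),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (inherits(table, "asv_table")) {
    out$group <- as.character(table$groups[out$sample])
    out <- out[, c("sample", "group", "richness", "shannon")]
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum |x - y| / sum (x + y)`; a semi-metric in `[0, 1]` for
#' non-negative inputs. Computed on per-sample relative abundances when
#' given a count table.
#'
#' @param table an [asv_table()], counts matrix, or proportion matrix.
#' @return Symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
bray_curtis <- function(table) {
  m <- as_counts(table)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative input",
                       call. = FALSE)
  if (inherits(table, "asv_table")) m <- relative_abundance(m)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering plus eigendecomposition of a distance matrix.
#' Negative eigenvalues (possible for semi-metrics such as Bray-Curtis)
#' are dropped from the variance denominator with a message.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param n_axes number of axes to return.
#' @return List of class `pcoa_result`: `coordinates` (samples x axes),
#'   `proportion_explained` (per returned axis, over positive
#'   eigenvalues), `eigenvalues`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("'d' must be a square symmetric distance matrix", call. = FALSE)
  }
  n_axes <- min(n_axes, nrow(d) - 1L)
  fit <- cmdscale(as.dist(d), k = n_axes, eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-10]
  if (any(eig < -1e-10)) {
    message(sprintf("pcoa: %d negative eigenvalue(s) dropped from the %s",
                    sum(eig < -1e-10), "variance denominator"))
  }
  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0) {
    stop("pcoa: no positive eigenvalues", call. = FALSE)
  }
  colnames(coords) <- paste0("PCoA", seq_len(ncol(coords)))
  prop <- (eig[seq_len(ncol(coords))] / sum(pos))
  structure(list(coordinates = coords,
                 proportion_explained = pmax(prop, 0),
                 eigenvalues = eig), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "samples,",
      ncol(x$coordinates), "axes\n")
  cat("proportion explained:",
      paste(sprintf("%.2f%%", 100 * x$proportion_explained),
            collapse = ", "), "\n")
  invisible(x)
}
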