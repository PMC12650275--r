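#' Signed Spearman-threshold adjacency network
#'
#' Edge (i, j) is present iff `|rho_ij| >= threshold`, with the signed
#' correlation as weight. Spearman rho uses average ranks for ties.
#' Constant columns (rho undefined) are excluded with a warning.
#'
#' @param abundances numeric matrix, samples x features (ASVs).
#' @param threshold correlation magnitude cutoff in (0, 1].
#' @return Object of class `signed_network`: `adjacency` (signed, zero
#'   where below threshold), `threshold`, `nodes`.
#' @export
spearman_adjacency <- function(abundances, threshold = 0.7) {
  m <- as_counts(abundances)
  if (nrow(m) < 4) stop("need >= 4 samples", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("excluding constant column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  rho <- cor(m, method = "spearman")
  adj <- ifelse(abs(rho) >= threshold, rho, 0)
  diag(adj) <- 0
  structure(list(adjacency = adj, threshold = threshold,
                 nodes = colnames(m)), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  n_edges <- sum(x$adjacency[upper.tri(x$adjacency)] != 0)
  cat(sprintf("signed_network: %d nodes, %d edges (|rho| >= %.3f)\n",
              length(x$nodes), n_edges, x$threshold))
  invisible(x)
}

as_igraph <- function(net, weights = c("abs", "signed", "none")) {
  weights <- match.arg(weights)
  w <- switch(weights, abs = abs(net$adjacency), signed = net$adjacency,
              none = (net$adjacency != 0) * 1)
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Detect modules in a signed network
#'
#' Greedy modularity-maximization communities on absolute edge weights
#' (deterministic under the network's stable node ordering). Modules
#' smaller than `min_size` are pooled into `"unassigned"`.
#'
#' @param net a [spearman_adjacency()] network.
#' @param min_size smallest retained module.
#' @param method "fast_greedy" (deterministic default) or "louvain"
#'   (seeded).
#' @param seed RNG seed, used by the louvain method only.
#' @return Named character vector node -> module id ("M1", "M2", ...,
#'   size-ordered) or `"unassigned"`.
#' @export
detect_modules <- function(net, min_size = 3L,
                           method = c("fast_greedy", "louvain"),
                           seed = 1L) {
  stopifnot(inherits(net, "signed_network"))
  method <- match.arg(method)
  g <- as_igraph(net, "abs")
  if (igraph::ecount(g) == 0) {
    return(setNames(rep("unassigned", length(net$nodes)), net$nodes))
  }
  comm <- if (method == "fast_greedy") {
    igraph::cluster_fast_greedy(g)
  } else {
    with_seed(seed, igraph::cluster_louvain(g))
  }
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= min_size]
  # size-descending, ties broken by community id for determinism
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  out <- setNames(rep("unassigned", length(memb)),
                  igraph::V(g)$name)
  for (i in seq_along(keep)) {
    out[memb == as.integer(keep[i])] <- paste0("M", i)
  }
  out
}

#' Module eigenvector (first principal component of a module)
#'
#' The per-sample summary of a module: first principal component of the
#' column-standardized member submatrix, sign-oriented so that the mean
#' correlation with the members is non-negative (the WGCNA eigengene
#' convention). Zero-variance members are dropped with a warning.
#'
#' @param abundances numeric matrix, samples x features.
#' @param members feature ids belonging to the module.
#' @param id optional module id carried into the result.
#' @return Object of class `module_eigenvector`: `scores` (per sample),
#'   `loadings` (unit norm), `variance_explained`, `members`, `id`.
#' @export
module_eigenvector <- function(abundances, members, id = NULL) {
  m <- as_counts(abundances)[, members, drop = FALSE]
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance member(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) < 1) stop("module has no variable members", call. = FALSE)
  z <- scale(m)
  sv <- svd(z, nu = 1, nv = 1)
  scores <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  mean_cor <- mean(cor(scores, z))
  if (mean_cor < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = setNames(scores, rownames(m)),
                 loadings = setNames(loadings, colnames(m)),
                 variance_explained = sv$d[1]^2 / sum(sv$d^2),
                 members = colnames(m), id = id),
            class = "module_eigenvector")
}

#' Phenotype trait blocks and their eigengenes
#'
#' Hierarchically clusters traits (average linkage on `1 - |Spearman
#' rho|`), cuts the tree to `n_blocks`, and computes one eigengene per
#' block as in [module_eigenvector()]. Block category labels are taken by
#' majority vote from the traits' category tags.
#'
#' @param phen numeric matrix, samples x traits (e.g. from
#'   [generate_phenotypes()]).
#' @param n_blocks number of trait blocks.
#' @param categories optional named vector trait -> category label;
#'   defaults to the matrix's `categories` attribute.
#' @return List of `phenotype_eigengene` objects (each: `scores`,
#'   `members`, `category`, `id`, `variance_explained`).
#' @export
phenotype_modules <- function(phen, n_blocks, categories = NULL) {
  phen <- as.matrix(phen)
  if (ncol(phen) < 2) stop("need >= 2 traits", call. = FALSE)
  if (n_blocks > ncol(phen)) {
    stop("n_blocks exceeds trait count", call. = FALSE)
  }
  if (is.null(categories)) categories <- attr(phen, "categories")
  rho <- cor(phen, method = "spearman")
  hc <- hclust(as.dist(1 - abs(rho)), method = "average")
  cut <- cutree(hc, k = n_blocks)
  out <- lapply(seq_len(n_blocks), function(b) {
    members <- names(cut)[cut == b]
    eg <- if (length(members) == 1) {
      list(scores = setNames(scale(phen[, members])[, 1], rownames(phen)),
           loadings = setNames(1, members), variance_explained = 1,
           members = members)
    } else {
      unclass(module_eigenvector(phen, members))
    }
    cat_lab <- if (!is.null(categories)) {
      names(sort(table(categories[members]), decreasing = TRUE))[1]
    } else NA_character_
    structure(c(eg[c("scores", "members", "variance_explained")],
                list(category = cat_lab, id = paste0("P", b))),
              class = "phenotype_eigengene")
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Mantel test between two distance matrices
#'
#' `r` is the Spearman correlation of the upper-triangle entries; the
#' permutation p-value jointly permutes rows and columns of `d2`:
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`. With `exact = TRUE` all
#' `n!` label permutations are enumerated instead (n <= 7) and
#' `p = #{r_perm >= r_obs} / n!`.
#'
#' @param d1,d2 symmetric distance matrices with identical labels.
#' @param n_perm number of random permutations.
#' @param seed RNG seed.
#' @param method correlation flavor ("spearman" default, "pearson"
#'   available).
#' @param exact enumerate all permutations instead of sampling.
#' @return List `(r, p, n_perm)`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L,
                        method = c("spearman", "pearson"), exact = FALSE) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!identical(dim(d1), dim(d2))) stop("dimension mismatch", call. = FALSE)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop("label mismatch between distance matrices", call. = FALSE)
  }
  n <- nrow(d1)
  if (n < 4) stop("need >= 4 objects", call. = FALSE)
  v1 <- upper_tri_vec(d1)
  r_obs <- cor(v1, upper_tri_vec(d2), method = method)
  stat <- function(perm) cor(v1, upper_tri_vec(d2[perm, perm]),
                             method = method)
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7", call. = FALSE)
    perms <- all_permutations(n)
    rs <- apply(perms, 1, stat)
    p <- mean(rs >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    rs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      stat(sample.int(n)), numeric(1)))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (1 + n_perm)
  }
  list(r = as.numeric(r_obs), p = p, n_perm = n_perm)
}

#' Link microbial module eigenvectors to phenotype eigengenes
#'
#' For every (microbial module, phenotype block) pair, reports both a
#' Mantel test on the Euclidean distances of the two eigenvectors and the
#' direct Spearman correlation of the scores. A pair is significant iff
#' both views agree: `|r| > r_threshold` and `p < p_threshold` for the
#' Mantel statistics and for the direct Spearman statistics. For each
#' significant microbial module, member features are ranked by the
#' magnitude of their correlation with their own module eigenvector
#' (module membership), giving the biomarker candidates.
#'
#' @param mes list of [module_eigenvector()] objects.
#' @param phen_eigens list of [phenotype_modules()] eigengenes.
#' @param abundances optional samples x features matrix used to rank
#'   biomarker members.
#' @param r_threshold,p_threshold significance thresholds (defaults 0.3
#'   and 0.05).
#' @param n_perm,seed Mantel permutations and seed.
#' @return data.frame of class `link_report` (columns `module`, `block`,
#'   `category`, `mantel_r`, `mantel_p`, `spearman_r`, `spearman_p`,
#'   `significant`) with attribute `biomarkers`: per significant module, a
#'   data.frame of members ranked by |membership|.
#' @export
link_modules <- function(mes, phen_eigens, abundances = NULL,
                         r_threshold = 0.3, p_threshold = 0.05,
                         n_perm = 999L, seed = 1L) {
  if (length(mes) == 0 || length(phen_eigens) == 0) {
    stop("need at least one module and one phenotype block", call. = FALSE)
  }
  rows <- list()
  k <- 0L
  for (me in mes) {
    for (pe in phen_eigens) {
      common <- intersect(names(me$scores), names(pe$scores))
      if (length(common) < 4) {
        stop("eigenvectors must share >= 4 samples", call. = FALSE)
      }
      dm <- as.matrix(dist(me$scores[common]))
      dp <- as.matrix(dist(pe$scores[common]))
      k <- k + 1L
      mt <- mantel_test(dm, dp, n_perm = n_perm, seed = sub_seed(seed, k))
      ct <- suppressWarnings(
        cor.test(me$scores[common], pe$scores[common], method = "spearman"))
      rows[[k]] <- data.frame(
        module = if (is.null(me$id)) paste0("M", k) else me$id,
        block = pe$id, category = pe$category,
        mantel_r = mt$r, mantel_p = mt$p,
        spearman_r = unname(ct$estimate), spearman_p = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- abs(out$mantel_r) > r_threshold &
    out$mantel_p < p_threshold &
    abs(out$spearman_r) > r_threshold &
    out$spearman_p < p_threshold
  biomarkers <- list()
  if (!is.null(abundances)) {
    for (me in mes) {
      if (!any(out$significant[out$module == me$id])) next
      sub <- as_counts(abundances)[names(me$scores), me$members,
                                   drop = FALSE]
      mm <- cor(sub, me$scores, method = "spearman")[, 1]
      biomarkers[[me$id]] <- data.frame(
        feature = names(sort(abs(mm), decreasing = TRUE)),
        membership = mm[names(sort(abs(mm), decreasing = TRUE))],
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  attr(out, "biomarkers") <- biomarkers
  class(out) <- c("link_report", "data.frame")
  out
}

#' Threshold sensitivity of module detection
#'
#' Rebuilds the Spearman network at a stricter threshold and reports, for
#' every base-threshold module, the best Jaccard overlap with any
#' alt-threshold module. A module is "recovered" iff its best Jaccard is
#' at least `jaccard_min`.
#'
#' @param abundances samples x features matrix.
#' @param base_threshold,alt_threshold correlation cutoffs
#'   (`alt > base`).
#' @param min_size passed to [detect_modules()].
#' @param jaccard_min recovery cutoff (default 0.5).
#' @return data.frame: `module`, `size`, `best_match`, `jaccard`,
#'   `recovered`; attribute `alt_empty` flags an edgeless alt network.
#' @export
sensitivity_check <- function(abundances, base_threshold = 0.7,
                              alt_threshold = 0.8, min_size = 3L,
                              jaccard_min = 0.5) {
  if (alt_threshold <= base_threshold) {
    stop("alt_threshold must exceed base_threshold", call. = FALSE)
  }
  base_mod <- detect_modules(spearman_adjacency(abundances, base_threshold),
                             min_size = min_size)
  alt_mod <- detect_modules(spearman_adjacency(abundances, alt_threshold),
                            min_size = min_size)
  base_ids <- setdiff(unique(base_mod), "unassigned")
  alt_ids <- setdiff(unique(alt_mod), "unassigned")
  rows <- lapply(base_ids, function(b) {
    mb <- names(base_mod)[base_mod == b]
    jac <- if (length(alt_ids)) {
      max(vapply(alt_ids, function(a) {
        ma <- names(alt_mod)[alt_mod == a]
        length(intersect(mb, ma)) / length(union(mb, ma))
      }, numeric(1)))
    } else 0
    best <- if (length(alt_ids)) {
      alt_ids[which.max(vapply(alt_ids, function(a) {
        ma <- names(alt_mod)[alt_mod == a]
        length(intersect(mb, ma)) / length(union(mb, ma))
      }, numeric(1)))]
    } else NA_character_
    data.frame(module = b, size = length(mb), best_match = best,
               jaccard = jac, recovered = jac >= jaccard_min,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), size = integer(0),
               best_match = character(0), jaccard = numeric(0),
               recovered = logical(0))
  attr(out, "alt_empty") <- length(alt_ids) == 0
  out
}
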