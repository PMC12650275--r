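#' RMT-style similarity threshold for a correlation matrix
#'
#' Scans a candidate grid for the smallest threshold at which the
#' thresholded matrix's eigenvalue nearest-neighbour spacing distribution
#' becomes Poisson-consistent (the random-matrix-theory transition from
#' correlated, GOE-like spectra to independent ones). Spacings are
#' computed after collapsing degenerate eigenvalues and spline unfolding;
#' Poisson consistency is a chi-square test of the spacings against the
#' unit exponential at p > 0.05. With `candidate_grid = NULL` the scan is
#' disabled and the configured fixed threshold is returned.
#'
#' @param corr_matrix symmetric correlation matrix.
#' @param candidate_grid increasing candidate thresholds, or `NULL` for
#'   fixed mode.
#' @param fixed threshold returned in fixed mode (default 0.995).
#' @param alpha Poisson-consistency level.
#' @return The chosen threshold (numeric scalar).
#' @export
rmt_threshold <- function(corr_matrix, candidate_grid = NULL,
                          fixed = 0.995, alpha = 0.05) {
  m <- as.matrix(corr_matrix)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("correlation matrix must be square and symmetric", call. = FALSE)
  }
  if (is.null(candidate_grid)) return(fixed)
  candidate_grid <- sort(candidate_grid)
  off <- abs(m[upper.tri(m)])
  if (max(off) < min(candidate_grid)) {
    warning("degenerate input: no correlation reaches the grid; ",
            "returning the fixed default", call. = FALSE)
    return(fixed)
  }
  for (t in candidate_grid) {
    a <- ifelse(abs(m) >= t, m, 0)
    diag(a) <- 1
    p <- spacing_poisson_p(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.na(p) && p > alpha) return(t)
  }
  warning("no candidate threshold passed the Poisson spacing test; ",
          "returning the grid maximum", call. = FALSE)
  max(candidate_grid)
}

# Chi-square p for "spacings follow the unit exponential": collapse
# degenerate eigenvalues, unfold via a smoothing spline of the spectral
# staircase, bin the spacings at exponential quantiles. NA when the
# spectrum is too degenerate to assess.
spacing_poisson_p <- function(ev, n_bins = 5L) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  n <- length(ev)
  if (n < 20) return(NA_real_)
  stair <- stats::smooth.spline(ev, seq_len(n), df = min(10, n - 1))
  unfolded <- stats::predict(stair, ev)$y
  s <- diff(unfolded)
  s <- s[s > 0]
  if (length(s) < 15) return(NA_real_)
  s <- s / mean(s)
  edges <- stats::qexp(seq(0, 1, length.out = n_bins + 1))
  obs <- table(cut(s, breaks = edges, include.lowest = TRUE))
  expd <- length(s) / n_bins
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  pchisq(stat, df = n_bins - 1, lower.tail = FALSE)
}

#' Topology metrics of a signed network
#'
#' The standard molecular-ecological-network panel: node and edge counts,
#' positive/negative edge percentages, average degree `2E/N`, average
#' local clustering coefficient on the unweighted skeleton (nodes of
#' degree < 2 contribute 0), modularity of the greedy partition on
#' absolute weights, module count (communities of two or more nodes), and
#' average shortest-path distance over connected pairs.
#'
#' @param net a `signed_network` (or symmetric signed adjacency matrix).
#' @return List of class `network_topology`.
#' @export
topology <- function(net) {
  if (!inherits(net, "signed_network")) {
    adj <- as.matrix(net)
    net <- structure(list(adjacency = adj, threshold = NA,
                          nodes = colnames(adj)), class = "signed_network")
  }
  w <- net$adjacency[upper.tri(net$adjacency)]
  n_edges <- sum(w != 0)
  if (n_edges == 0) stop("empty network", call. = FALSE)
  g <- as_igraph(net, "abs")
  n <- igraph::vcount(g)
  pos <- sum(w > 0)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  comm <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(comm)
  structure(list(
    n_nodes = n,
    n_edges = n_edges,
    positive_pct = round(100 * pos / n_edges, 2),
    negative_pct = round(100 * (n_edges - pos) / n_edges, 2),
    avg_degree = 2 * n_edges / n,
    avg_clustering = mean(cc),
    modularity = igraph::modularity(comm),
    n_modules = sum(table(memb) >= 2),
    avg_path_distance = igraph::mean_distance(g, weights = NA,
                                              unconnected = TRUE)),
    class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("network topology\n")
  cat(sprintf("  nodes %d, edges %d (%.2f%% pos / %.2f%% neg)\n",
              x$n_nodes, x$n_edges, x$positive_pct, x$negative_pct))
  cat(sprintf("  avgK %.3f  avgCC %.3f  M %.3f (%d modules)  GD %.3f\n",
              x$avg_degree, x$avg_clustering, x$modularity, x$n_modules,
              x$avg_path_distance))
  invisible(x)
}

#' Random-network null distribution for topology metrics
#'
#' Degree-preserving edge rewiring (double-edge swaps, `10 * edges` swap
#' attempts per randomization) of the unweighted skeleton; clustering
#' coefficient, modularity and average path distance are recomputed per
#' randomization. Graphs with fewer than two edges fall back to
#' Erdos-Renyi graphs of the same size, with a warning.
#'
#' @param net a `signed_network`.
#' @param n_rand number of randomizations.
#' @param seed RNG seed.
#' @return Object of class `null_distribution`: data.frame of metric
#'   mean/sd plus the per-randomization draws.
#' @export
random_null <- function(net, n_rand = 100L, seed = 1L) {
  stopifnot(inherits(net, "signed_network"))
  g <- as_igraph(net, "none")
  ne <- igraph::ecount(g)
  er_fallback <- ne < 2
  if (er_fallback) {
    warning("graph too small to rewire; using Erdos-Renyi null",
            call. = FALSE)
  }
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_rand), function(i) {
      r <- if (er_fallback) {
        igraph::sample_gnm(igraph::vcount(g), ne)
      } else {
        igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
      }
      comm <- igraph::cluster_fast_greedy(r)
      c(avgCC = mean(igraph::transitivity(r, type = "localundirected",
                                          isolates = "zero")),
        M = igraph::modularity(comm),
        GD = igraph::mean_distance(r, weights = NA, unconnected = TRUE))
    }, numeric(3)))
  })
  structure(list(
    summary = data.frame(metric = colnames(draws),
                         mean = colMeans(draws),
                         sd = apply(draws, 2, sd), row.names = NULL),
    draws = draws, n_rand = n_rand), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("random-network null (", x$n_rand, " randomizations)\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %s: %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  }
  invisible(x)
}

#' Cross-group module similarity by Fisher's exact test
#'
#' For every module pair across two different group networks, a 2x2 table
#' (shared members vs exclusive members vs the rest of the union node
#' universe) is tested by a one-sided Fisher's exact test for overlap
#' enrichment. Pairs with p < `alpha` are "similar"; similar pairs are
#' merged into clusters by transitive closure, and the retained
#' percentage is `100 * similar pairs / total pairs` (2 decimals).
#'
#' @param partitions named list, one membership vector (node -> module
#'   id, `"unassigned"` ignored) per group network.
#' @param alpha similarity level.
#' @return List of class `module_pair_report`: `pairs` data.frame,
#'   `clusters` (list of module labels per cluster), `n_pairs`,
#'   `n_retained`, `retained_pct`.
#' @export
module_similarity <- function(partitions, alpha = 0.05) {
  if (length(partitions) < 2) stop("need >= 2 partitions", call. = FALSE)
  if (is.null(names(partitions))) {
    names(partitions) <- paste0("net", seq_along(partitions))
  }
  universe <- unique(unlist(lapply(partitions, names)))
  mods <- list()
  for (g in names(partitions)) {
    p <- partitions[[g]]
    for (m in setdiff(unique(p), "unassigned")) {
      mods[[paste0(g, ":", m)]] <- names(p)[p == m]
    }
  }
  if (length(mods) &&
      !any(duplicated(unlist(lapply(partitions, names)))) &&
      length(partitions) > 1) {
    # fully disjoint node universes cannot overlap
    if (all(vapply(names(partitions), function(g)
      length(intersect(names(partitions[[g]]),
                       unlist(lapply(partitions[setdiff(names(partitions), g)],
                                     names)))) == 0, logical(1)))) {
      warning("node universes are disjoint; all pairs non-similar",
              call. = FALSE)
    }
  }
  groups_of <- sub(":.*$", "", names(mods))
  rows <- list()
  k <- 0L
  ids <- names(mods)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i || groups_of[i] == groups_of[j]) next
      a <- mods[[i]]; b <- mods[[j]]
      shared <- length(intersect(a, b))
      tab <- matrix(c(shared, length(a) - shared, length(b) - shared,
                      length(universe) - length(union(a, b))), 2, 2)
      p <- fisher.test(tab, alternative = "greater")$p.value
      k <- k + 1L
      rows[[k]] <- data.frame(module_a = ids[i], module_b = ids[j],
                              shared = shared, p = p,
                              similar = p < alpha, stringsAsFactors = FALSE)
    }
  }
  pairs <- if (k) do.call(rbind, rows) else
    data.frame(module_a = character(0), module_b = character(0),
               shared = integer(0), p = numeric(0), similar = logical(0))
  # transitive closure of similar pairs -> clusters
  clusters <- list()
  if (any(pairs$similar)) {
    sg <- igraph::graph_from_data_frame(
      pairs[pairs$similar, c("module_a", "module_b")], directed = FALSE,
      vertices = data.frame(name = ids))
    comp <- igraph::components(sg)
    for (c_id in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == c_id]
      if (length(members) >= 2) clusters <- c(clusters, list(members))
    }
  }
  structure(list(pairs = pairs, clusters = clusters,
                 n_pairs = nrow(pairs), n_retained = sum(pairs$similar),
                 retained_pct = round(100 * sum(pairs$similar) /
                                        max(nrow(pairs), 1L), 2)),
            class = "module_pair_report")
}

#' @export
print.module_pair_report <- function(x, ...) {
  cat(sprintf("module pairs: %d tested, %d similar (%.2f%%), %d cluster(s)\n",
              x$n_pairs, x$n_retained, x$retained_pct, length(x$clusters)))
  invisible(x)
}

#' Positive/negative edge percentages
#'
#' @param net a `signed_network`.
#' @return Named numeric `c(positive_pct, negative_pct)`, 2 decimals,
#'   summing to 100.
#' @export
edge_sign_summary <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  w <- net$adjacency[upper.tri(net$adjacency)]
  w <- w[w != 0]
  if (length(w) == 0) stop("empty network", call. = FALSE)
  c(positive_pct = round(100 * sum(w > 0) / length(w), 2),
    negative_pct = round(100 * sum(w < 0) / length(w), 2))
}
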