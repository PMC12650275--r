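# Independent oracles and fixtures used across the suite. Everything here
# is deliberately brute-force and separate from the package's code paths.

# Presence-pattern fixture reproducing the published four-group UpSet
# arithmetic: 1504 ASVs, 22 common to all groups, uniques 1115/29/51/196,
# 19 triple-membership ASVs in {CK, LSF, HSF}, and pair memberships
# CK-HFD 21, CK-LSF 16, CK-HSF 19, HFD-LSF 16. Group totals come out as
# 1212 / 88 / 124 / 256.
upset_fixture_table <- function() {
  groups <- c("CK", "HFD", "LSF", "HSF")
  membership <- list()
  add <- function(sets, n) {
    for (i in seq_len(n)) membership[[length(membership) + 1L]] <<- sets
  }
  add(groups, 22)
  add("CK", 1115); add("HFD", 29); add("LSF", 51); add("HSF", 196)
  add(c("CK", "LSF", "HSF"), 19)
  add(c("CK", "HFD"), 21)
  add(c("CK", "LSF"), 16)
  add(c("CK", "HSF"), 19)
  add(c("HFD", "LSF"), 16)
  counts <- matrix(0L, nrow = length(groups), ncol = length(membership),
                   dimnames = list(groups,
                                   sprintf("ASV%04d", seq_along(membership))))
  for (j in seq_along(membership)) counts[membership[[j]], j] <- 1L
  asv_table(counts, setNames(groups, groups))
}

# Set-algebra oracle for the group partition report.
partition_oracle <- function(table) {
  pooled <- rowsum(table$counts, table$groups)
  presence <- pooled > 0
  totals <- rowSums(presence)
  list(total = totals,
       unique = sapply(rownames(presence), function(g)
         sum(presence[g, ] & colSums(presence) == 1L)),
       common = sum(colSums(presence) == nrow(presence)),
       share = round(100 * totals / sum(totals), 2))
}

# Brute-force graph topology on a signed adjacency matrix.
brute_topology <- function(adj) {
  a <- (adj != 0) * 1L
  diag(a) <- 0L
  n <- nrow(a)
  deg <- rowSums(a)
  n_edges <- sum(a) / 2
  # local clustering by neighbour-pair counting; degree < 2 contributes 0
  cc <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    links / choose(length(nb), 2)
  }, numeric(1))
  # all-pairs shortest paths via Floyd-Warshall on the unweighted skeleton
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  w <- adj[upper.tri(adj)]
  w <- w[w != 0]
  list(n_nodes = n, n_edges = n_edges, avg_degree = 2 * n_edges / n,
       avg_clustering = mean(cc),
       gd = if (length(finite)) mean(finite) else NaN,
       positive_pct = round(100 * sum(w > 0) / length(w), 2))
}

# Newman modularity of a given partition, from the definition.
brute_modularity <- function(adj, membership) {
  a <- abs(adj)
  diag(a) <- 0
  m2 <- sum(a)
  k <- rowSums(a)
  q <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) {
    if (membership[i] == membership[j]) {
      q <- q + a[i, j] - k[i] * k[j] / m2
    }
  }
  unname(q / m2)
}

# Spearman rho from the textbook rank formula with average ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# One-sided enrichment p as an explicit hypergeometric tail sum.
hyper_tail_p <- function(shared, size_a, size_b, universe) {
  sum(dhyper(shared:min(size_a, size_b), size_a, universe - size_a, size_b))
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n <- length(a)
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small deterministic ASV table for unit tests.
toy_table <- function() {
  counts <- matrix(c(10L, 5L, 0L, 2L,
                     8L,  4L, 1L, 0L,
                     0L,  6L, 3L, 3L,
                     1L,  7L, 2L, 2L,
                     5L,  0L, 4L, 1L,
                     4L,  1L, 5L, 0L),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(paste0("s", 1:6), paste0("ASV", 1:4)))
  asv_table(counts, setNames(rep(c("A", "B", "C"), each = 2),
                             paste0("s", 1:6)))
}
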