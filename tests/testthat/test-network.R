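test_that("topology matches hand enumeration on small graphs", {
  tri <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tri[upper.tri(tri)] <- 0.9
  tri <- tri + t(tri)
  topo <- topology(tri)
  expect_equal(topo$n_nodes, 3)
  expect_equal(topo$n_edges, 3)
  expect_equal(topo$avg_degree, 2)
  expect_equal(topo$avg_clustering, 1)
  expect_equal(topo$avg_path_distance, 1)
  expect_equal(topo$positive_pct, 100)
  # 3-node path
  path <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  path["a", "b"] <- path["b", "a"] <- 0.8
  path["b", "c"] <- path["c", "b"] <- -0.8
  tp <- topology(path)
  expect_equal(tp$avg_degree, 4 / 3)
  expect_equal(tp$avg_clustering, 0)
  expect_equal(tp$avg_path_distance, (1 + 1 + 2) / 3)
  expect_equal(tp$positive_pct, 50)
  expect_error(topology(matrix(0, 2, 2)), "empty")
})

test_that("topology agrees with the brute-force oracle on random graphs", {
  for (i in 1:20) {
    set.seed(i)
    n <- sample(5:12, 1)
    adj <- matrix(0, n, n)
    idx <- which(upper.tri(adj))
    on <- sample(idx, max(2, rbinom(1, length(idx), 0.35)))
    adj[on] <- runif(length(on), 0.5, 1) * sample(c(-1, 1), length(on),
                                                 replace = TRUE)
    adj <- adj + t(adj)
    dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
    topo <- topology(adj)
    oracle <- brute_topology(adj)
    expect_equal(topo$n_edges, oracle$n_edges)
    expect_equal(topo$avg_degree, oracle$avg_degree)
    expect_equal(topo$avg_clustering, oracle$avg_clustering,
                 tolerance = 1e-12)
    expect_equal(topo$avg_path_distance, oracle$gd, tolerance = 1e-12)
    expect_equal(topo$positive_pct, oracle$positive_pct)
  }
})

test_that("reported modularity equals the definition on its partition", {
  set.seed(2)
  f <- matrix(rnorm(40 * 2), 40, 2)
  x <- do.call(cbind, lapply(1:2, function(b)
    f[, b] + matrix(rnorm(40 * 5, 0, 0.3), 40, 5)))
  colnames(x) <- paste0("v", 1:10)
  net <- spearman_adjacency(x, 0.5)
  g <- gutlink:::as_igraph(net, "abs")
  comm <- igraph::cluster_fast_greedy(g)
  expect_equal(topology(net)$modularity,
               brute_modularity(net$adjacency, igraph::membership(comm)),
               tolerance = 1e-10)
})

test_that("the degree-preserving null keeps degrees and flags structure", {
  set.seed(3)
  f <- matrix(rnorm(40 * 3), 40, 3)
  x <- do.call(cbind, lapply(1:3, function(b)
    f[, b] + matrix(rnorm(40 * 6, 0, 0.3), 40, 6)))
  colnames(x) <- paste0("v", 1:18)
  net <- spearman_adjacency(x, 0.5)
  g <- gutlink:::as_igraph(net, "none")
  deg <- sort(igraph::degree(g))
  # degree sequence preserved in every randomization
  with(list(), {
    set.seed(1)
    for (i in 1:10) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 *
                                                      igraph::ecount(g)))
      expect_equal(sort(igraph::degree(r)), deg)
    }
  })
  # planted-modular graph: empirical modularity above the null band
  topo <- topology(net)
  null <- random_null(net, n_rand = 50, seed = 2)
  m_row <- null$summary[null$summary$metric == "M", ]
  expect_gt(topo$modularity, m_row$mean + 2 * m_row$sd)
  # complete graph: rewiring is the identity, sd = 0
  comp <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(comp) <- 0
  cnet <- structure(list(adjacency = comp, threshold = 0.5,
                         nodes = letters[1:4]), class = "signed_network")
  cnull <- random_null(cnet, n_rand = 10, seed = 1)
  expect_true(all(cnull$summary$sd == 0))
})

test_that("an unstructured random graph does not beat its null", {
  set.seed(8)
  n <- 30
  adj <- matrix(0, n, n, dimnames = list(paste0("n", 1:n),
                                         paste0("n", 1:n)))
  idx <- which(upper.tri(adj))
  on <- sample(idx, 60)
  adj[on] <- runif(60, 0.5, 1)
  adj <- adj + t(adj)
  net <- structure(list(adjacency = adj, threshold = 0.5,
                        nodes = rownames(adj)), class = "signed_network")
  topo <- topology(net)
  null <- random_null(net, n_rand = 50, seed = 3)
  m_row <- null$summary[null$summary$metric == "M", ]
  expect_lt(topo$modularity, m_row$mean + 3 * m_row$sd)
})

test_that("Fisher module similarity matches the hypergeometric tail", {
  universe <- paste0("n", 1:40)
  # identical 12-node modules over a 40-node universe
  p1b <- setNames(c(rep("M1", 12), rep("unassigned", 28)), universe)
  p2b <- setNames(c(rep("A", 12), rep("unassigned", 28)), universe)
  msb <- module_similarity(list(g1 = p1b, g2 = p2b))
  expect_equal(msb$pairs$p[1], hyper_tail_p(12, 12, 12, 40),
               tolerance = 1e-12)
  expect_true(msb$pairs$similar[1])
  # disjoint modules: one-sided p = 1, not similar
  p3 <- setNames(c(rep("B", 12), rep("unassigned", 28)),
                 universe[c(13:24, 1:12, 25:40)])
  ms3 <- module_similarity(list(g1 = p1b, g2 = p3))
  expect_equal(ms3$pairs$p[1], 1)
  expect_false(ms3$pairs$similar[1])
})

test_that("retained module pairs are reported as a percentage", {
  # 5 x 10 modules over a large universe; exactly 3 heavily overlapping
  # cross-group pairs -> 3 of 50 retained, 6.00%
  universe <- paste0("n", 1:500)
  g1 <- setNames(rep(paste0("M", 1:5), each = 10), universe[1:50])
  g2_nodes <- c(universe[1:30], universe[101:170])
  g2 <- setNames(rep(paste0("K", 1:10), each = 10), g2_nodes)
  pad1 <- setNames(rep("unassigned", 450), universe[51:500])
  pad2 <- setNames(rep("unassigned", 400), setdiff(universe, g2_nodes))
  ms <- module_similarity(list(g1 = c(g1, pad1), g2 = c(g2, pad2)))
  expect_equal(ms$n_pairs, 50)
  expect_equal(ms$n_retained, 3)
  expect_equal(ms$retained_pct, 6.00)
  expect_length(ms$clusters, 3)
})

test_that("edge sign percentages follow the arithmetic", {
  mk <- function(w) {
    n <- length(w) + 1
    adj <- matrix(0, n, n)
    for (i in seq_along(w)) adj[i, i + 1] <- adj[i + 1, i] <- w[i]
    dimnames(adj) <- list(paste0("n", 1:n), paste0("n", 1:n))
    structure(list(adjacency = adj, threshold = 0.5,
                   nodes = rownames(adj)), class = "signed_network")
  }
  expect_equal(unname(edge_sign_summary(mk(rep(0.8, 5)))), c(100, 0))
  expect_equal(unname(edge_sign_summary(mk(c(rep(0.8, 10), -0.8)))),
               c(90.91, 9.09))
  expect_equal(unname(edge_sign_summary(mk(c(0.8, -0.8)))), c(50, 50))
})

test_that("the RMT scan separates planted blocks from noise", {
  set.seed(7)
  n <- 60
  f <- matrix(rnorm(n * 5), n, 5)
  x <- cbind(do.call(cbind, lapply(1:5, function(b)
    f[, b] + matrix(rnorm(n * 8, 0, 0.25), n, 8))),
    matrix(rnorm(n * 40), n, 40))
  cm <- cor(x)
  grid <- seq(0.4, 0.95, by = 0.05)
  th <- rmt_threshold(cm, candidate_grid = grid)
  expect_true(th %in% grid)
  # at the chosen threshold the within-block edges survive and almost all
  # of the noise background is gone
  blocks <- rep(1:5, each = 8)
  within <- abs(cm[1:40, 1:40])[outer(blocks, blocks, "==") &
                                  upper.tri(cm[1:40, 1:40])]
  noise <- abs(cm[41:80, 41:80][upper.tri(cm[41:80, 41:80])])
  expect_gt(mean(within >= th), 0.95)
  expect_lt(mean(noise >= th), 0.05)
  # fixed mode and degenerate input
  expect_equal(rmt_threshold(cm), 0.995)
  expect_warning(out <- rmt_threshold(diag(10),
                                      candidate_grid = seq(0.4, 0.9, 0.1)),
                 "degenerate")
  expect_equal(out, 0.995)
  expect_error(rmt_threshold(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
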