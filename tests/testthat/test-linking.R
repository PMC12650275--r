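test_that("Spearman adjacency follows the rank formula and threshold", {
  set.seed(1)
  n <- 8
  x <- rnorm(n)
  m <- cbind(a = x, b = x + rnorm(n, 0, 1e-6), c = rnorm(n),
             d = rep(2, n), e = c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_warning(net <- spearman_adjacency(m, 0.7), "constant")
  expect_false("d" %in% net$nodes)
  # perfectly monotone pair: rho = 1, edge present
  expect_equal(net$adjacency["a", "b"], 1)
  # tied vector: rho equals the brute-force average-rank formula
  rho_oracle <- brute_spearman(m[, "a"], m[, "e"])
  full <- suppressWarnings(spearman_adjacency(m, 0.01))
  expect_equal(full$adjacency["a", "e"], rho_oracle, tolerance = 1e-12)
  expect_error(spearman_adjacency(m[1:3, ], 0.7), ">= 4")
  expect_error(spearman_adjacency(m, 1.5), "0, 1")
})

test_that("module detection finds planted blocks and pools small ones", {
  # two disconnected cliques
  adj <- matrix(0, 8, 8, dimnames = list(letters[1:8], letters[1:8]))
  adj[1:4, 1:4] <- 0.9; adj[5:8, 5:8] <- 0.9; diag(adj) <- 0
  net <- structure(list(adjacency = adj, threshold = 0.7,
                        nodes = letters[1:8]), class = "signed_network")
  mods <- detect_modules(net, min_size = 3)
  expect_length(setdiff(unique(mods), "unassigned"), 2)
  expect_length(unique(mods[1:4]), 1)
  expect_length(unique(mods[5:8]), 1)
  # ring of 4 below min_size: everything unassigned
  ring <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ring[cbind(1:4, c(2, 3, 4, 1))] <- 0.8
  ring <- pmax(ring, t(ring))
  net2 <- structure(list(adjacency = ring, threshold = 0.7,
                         nodes = letters[1:4]), class = "signed_network")
  expect_true(all(detect_modules(net2, min_size = 5) == "unassigned"))
  # planted three-block correlation structure: high Adjusted Rand recovery
  aris <- vapply(1:10, function(i) {
    set.seed(i)
    f <- matrix(rnorm(40 * 3), 40, 3)
    x <- do.call(cbind, lapply(1:3, function(b)
      f[, b] + matrix(rnorm(40 * 8, 0, 0.4), 40, 8)))
    colnames(x) <- paste0("v", 1:24)
    truth <- rep(1:3, each = 8)
    mods_i <- detect_modules(spearman_adjacency(x, 0.5), min_size = 3)
    adjusted_rand(mods_i, truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("module eigenvectors obey the WGCNA conventions", {
  set.seed(5)
  x <- rnorm(10)
  # identical columns: scores equal the standardized column, variance 1
  m <- cbind(a = x, b = x, c = x)
  rownames(m) <- paste0("s", 1:10)
  me <- module_eigenvector(m, c("a", "b", "c"), id = "M1")
  expect_equal(me$variance_explained, 1)
  expect_equal(unname(cor(me$scores, x)), 1, tolerance = 1e-12)
  expect_equal(sum(me$loadings^2), 1, tolerance = 1e-12)
  # 2-member module vs closed-form 2x2 eigendecomposition
  m2 <- cbind(a = x, b = x + rnorm(10))
  rownames(m2) <- paste0("s", 1:10)
  me2 <- module_eigenvector(m2, c("a", "b"))
  r <- cor(scale(m2))[1, 2]
  expect_equal(me2$variance_explained, (1 + abs(r)) / 2, tolerance = 1e-10)
  # sign convention: flipping all member columns leaves the output invariant
  m3 <- -m2
  me3 <- module_eigenvector(m3, c("a", "b"))
  expect_gte(mean(cor(me2$scores, scale(m2))), 0)
  expect_gte(mean(cor(me3$scores, scale(m3))), 0)
  # zero-variance member dropped with a warning
  m4 <- cbind(m2, z = rep(1, 10))
  expect_warning(module_eigenvector(m4, c("a", "b", "z")), "zero-variance")
})

test_that("phenotype blocks recover planted trait structure", {
  set.seed(9)
  n <- 30
  f1 <- rnorm(n); f2 <- rnorm(n)
  phen <- cbind(t1 = f1, t2 = f1 + rnorm(n, 0, 1e-8),
                t3 = f2, t4 = f2 + rnorm(n, 0, 1e-8))
  rownames(phen) <- paste0("s", 1:n)
  pes <- phenotype_modules(phen, 2,
                           categories = c(t1 = "Gut health",
                                          t2 = "Gut health",
                                          t3 = "Gut development",
                                          t4 = "Gut development"))
  members <- lapply(pes, `[[`, "members")
  expect_true(any(vapply(members, setequal, logical(1), c("t1", "t2"))))
  expect_true(any(vapply(members, setequal, logical(1), c("t3", "t4"))))
  cats <- vapply(pes, `[[`, character(1), "category")
  expect_setequal(unname(cats), c("Gut health", "Gut development"))
  # degenerate single block: the global first PC
  one <- phenotype_modules(phen, 1)
  expect_length(one, 1)
  expect_setequal(one[[1]]$members, colnames(phen))
  expect_error(phenotype_modules(phen, 9), "exceeds")
  # planted generator blocks recovered at the planted count
  cfg <- synth_config(module_phenotype_r = 0.95, noise_sd = 0.3, seed = 2L)
  s <- generate_asv_table(cfg)
  phen2 <- generate_phenotypes(s$truth, cfg)
  pes2 <- phenotype_modules(phen2, 10)
  blocks <- attr(phen2, "trait_blocks")
  linked <- names(blocks)[!is.na(blocks)]
  hit <- vapply(pes2, function(pe) all(linked %in% pe$members), logical(1))
  expect_true(any(hit))
})

test_that("the Mantel test is exact under enumeration and matches vegan", {
  d1 <- as.matrix(dist(c(1, 2, 3, 5)))
  d2 <- as.matrix(dist(c(1.2, 2.1, 3.3, 4.9)))
  mt <- mantel_test(d1, d2, exact = TRUE)
  # independent enumeration oracle
  perms <- gutlink:::all_permutations(4)
  v1 <- d1[upper.tri(d1)]
  rs <- apply(perms, 1, function(p)
    cor(v1, d2[p, p][upper.tri(d2)], method = "spearman"))
  expect_equal(mt$p, mean(rs >= mt$r - 1e-12))
  expect_equal(mt$n_perm, 24)
  # n = 5 exactness too
  d3 <- as.matrix(dist(c(1, 4, 2, 8, 5)))
  d4 <- as.matrix(dist(c(2, 3, 1, 9, 4)))
  mt5 <- mantel_test(d3, d4, exact = TRUE)
  perms5 <- gutlink:::all_permutations(5)
  v3 <- d3[upper.tri(d3)]
  rs5 <- apply(perms5, 1, function(p)
    cor(v3, d4[p, p][upper.tri(d4)], method = "spearman"))
  expect_equal(mt5$p, mean(rs5 >= mt5$r - 1e-12))
  # identity: r = 1
  expect_equal(mantel_test(d1, d1, n_perm = 99)$r, 1)
  # statistic agrees with vegan's spearman Mantel r
  set.seed(11)
  a <- as.matrix(dist(rnorm(8))); b <- as.matrix(dist(rnorm(8)))
  expect_equal(mantel_test(a, b, n_perm = 9)$r,
               unname(vegan::mantel(a, b, method = "spearman",
                                    permutations = 9)$statistic),
               tolerance = 1e-10)
  expect_error(mantel_test(d1, d2[c(2, 1, 3, 4), c(2, 1, 3, 4)]), "label")
})

test_that("module-phenotype links are reported with biomarker ranking", {
  set.seed(31)
  n <- 12
  scores <- rnorm(n)
  names(scores) <- paste0("s", 1:n)
  me <- structure(list(scores = scores, members = paste0("a", 1:4),
                       id = "M1"), class = "module_eigenvector")
  pe_hit <- structure(list(scores = scores, members = "t1", id = "P1",
                           category = "Gut health"),
                      class = "phenotype_eigengene")
  pe_null <- structure(list(scores = setNames(rnorm(n), names(scores)),
                            members = "t2", id = "P2",
                            category = "Gut health"),
                       class = "phenotype_eigengene")
  abund <- sapply(1:4, function(k) scores * (5 - k) / 4 + rnorm(n, 0, 0.3))
  colnames(abund) <- paste0("a", 1:4)
  rownames(abund) <- names(scores)
  lk <- link_modules(list(me), list(pe_hit, pe_null), abundances = abund,
                     n_perm = 199, seed = 4)
  hit <- lk[lk$block == "P1", ]
  expect_equal(hit$mantel_r, 1, tolerance = 1e-9)
  expect_equal(hit$spearman_r, 1, tolerance = 1e-9)
  expect_true(hit$significant)
  bm <- attr(lk, "biomarkers")$M1
  expect_setequal(bm$feature, paste0("a", 1:4))
  expect_true(all(diff(abs(bm$membership)) <= 1e-12))
})

test_that("a planted linked module is recovered end to end (fixed seed)", {
  cfg <- synth_config(noise_sd = 0.3, module_phenotype_r = 0.9, seed = 4L)
  s <- generate_asv_table(cfg)
  abund <- relative_abundance(s$table)[, names(s$truth$module_membership)]
  mods <- detect_modules(spearman_adjacency(abund, 0.7))
  ids <- setdiff(unique(mods), "unassigned")
  mes <- lapply(ids, function(m)
    module_eigenvector(abund, names(mods)[mods == m], id = m))
  phen <- generate_phenotypes(s$truth, cfg)
  pes <- phenotype_modules(phen, 10)
  lk <- link_modules(mes, pes, abundances = abund, n_perm = 199, seed = 4)
  planted_asvs <- names(s$truth$module_membership)[
    s$truth$module_membership == "M1"]
  planted_mod <- ids[which.max(vapply(ids, function(m)
    sum(names(mods)[mods == m] %in% planted_asvs), numeric(1)))]
  blocks <- attr(phen, "trait_blocks")
  planted_block <- names(pes)[which.max(vapply(pes, function(pe)
    sum(pe$members %in% names(blocks)[!is.na(blocks)]), numeric(1)))]
  sig <- lk[lk$significant, ]
  expect_true(any(sig$module == planted_mod & sig$block == planted_block))
  # its top-ranked biomarkers are planted module members
  bm <- attr(lk, "biomarkers")[[planted_mod]]
  expect_true(all(head(bm$feature, 3) %in% planted_asvs))
})

test_that("strong modules survive the stricter network threshold", {
  set.seed(6)
  f <- matrix(rnorm(30 * 2), 30, 2)
  x <- do.call(cbind, lapply(1:2, function(b)
    f[, b] + matrix(rnorm(30 * 6, 0, 0.2), 30, 6)))
  colnames(x) <- paste0("v", 1:12)
  sens <- sensitivity_check(x, 0.7, 0.8, min_size = 3)
  expect_true(all(sens$recovered))
  expect_true(all(sens$jaccard >= 0.5))
  # edgeless alternative network: nothing recovered, flag set
  set.seed(7)
  noise <- matrix(rnorm(200 * 10), 200, 10,
                  dimnames = list(NULL, paste0("n", 1:10)))
  sens2 <- sensitivity_check(noise, 0.25, 0.9, min_size = 2)
  expect_true(attr(sens2, "alt_empty") || all(!sens2$recovered) ||
                nrow(sens2) == 0)
  expect_error(sensitivity_check(x, 0.8, 0.7), "exceed")
})
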