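test_that("paired_tmap matches the direct per-cell formula", {
  set.seed(10)
  a <- array(rnorm(3 * 2 * 4, 1), c(3, 2, 4))
  b <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  tm <- paired_tmap(a, b)
  expect_equal(tm$df, 2)
  for (c0 in 1:2) for (s0 in 1:4) {
    d <- a[, c0, s0] - b[, c0, s0]
    expect_equal(tm$values[c0, s0], mean(d) / (sd(d) / sqrt(3)),
                 tolerance = 1e-12)
  }
  # identical inputs: zero-variance cells are flagged NA
  expect_true(all(is.na(paired_tmap(a, a)$values)))
  # constant per-subject shift: t identical across cells
  shift <- a + array(rep(c(1, 2, 4), 2 * 4), c(3, 2, 4))
  tmc <- paired_tmap(shift, a)
  expect_equal(max(tmc$values) - min(tmc$values), 0, tolerance = 1e-9)
  expect_error(paired_tmap(a, b[1:2, , ]), "identical dimensions")
})

test_that("adjacency is a symmetric irreflexive distance-threshold relation", {
  m <- montage(c("a", "b", "c"), rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  adj <- build_adjacency(m, radius = 1.1)
  expect_true(adj["a", "b"] && adj["b", "c"])
  expect_false(adj["a", "c"])
  expect_false(any(diag(adj)))
  expect_equal(adj, t(adj), ignore_attr = TRUE)
  expect_warning(build_adjacency(m, radius = 0.5), "no edges")
  # default radius connects the full hd129 cap (graph-traversal oracle)
  hm <- default_montage("hd129")
  g <- igraph::graph_from_adjacency_matrix(build_adjacency(hm), "undirected")
  expect_true(igraph::is_connected(g))
})

test_that("find_clusters equals the flood-fill oracle on random t-maps", {
  set.seed(11)
  adj <- toy_adjacency_chain(3)
  for (rep in 1:25) {
    tm <- matrix(rnorm(12, sd = 2), 3, 4)
    got <- find_clusters(tm, t_crit = 1.5, adj)
    want <- oracle_find_clusters(tm, 1.5, adj)
    expect_equal(length(got), length(want))
    expect_equal(sort(vapply(got, `[[`, numeric(1), "mass")),
                 sort(vapply(want, `[[`, numeric(1), "mass")),
                 tolerance = 1e-12)
    # union of clusters = supra-threshold set, clusters disjoint
    cells <- do.call(rbind, lapply(got, `[[`, "members"))
    ids <- if (is.null(cells)) integer(0) else cells[, 1] + (cells[, 2] - 1) * 3
    expect_equal(sort(unname(ids)), which(abs(tm) > 1.5))
    expect_false(anyDuplicated(ids) > 0)
    # sign homogeneity
    for (cl in got)
      expect_true(all(sign(tm[cl$members]) == ifelse(cl$sign == "positive", 1, -1)))
  }
  # degenerate cases
  expect_length(find_clusters(matrix(0.1, 3, 4), 1.5, adj), 0)
  single <- matrix(0, 3, 4); single[2, 2] <- 3
  got1 <- find_clusters(single, 1.5, adj)
  expect_length(got1, 1)
  expect_equal(got1[[1]]$mass, 3)
})

test_that("two supra-threshold islands stay separate clusters", {
  adj <- toy_adjacency_chain(3)
  tm <- matrix(0, 3, 4)
  tm[1, 1:2] <- 4           # island one: channel 1, samples 1-2
  tm[3, 4] <- 5             # island two: far corner
  cl <- find_clusters(tm, 2, adj)
  expect_length(cl, 2)
  expect_equal(sort(vapply(cl, `[[`, numeric(1), "mass")), c(5, 8))
})

test_that("raising t_crit never grows a cluster", {
  set.seed(12)
  adj <- toy_adjacency_chain(4)
  tm <- matrix(rnorm(24, sd = 2), 4, 6)
  lo <- find_clusters(tm, 1, adj)
  hi <- find_clusters(tm, 2, adj)
  expect_lte(sum(vapply(hi, function(c) nrow(c$members), numeric(1))),
             sum(vapply(lo, function(c) nrow(c$members), numeric(1))))
})

test_that("critical_t matches the t quantile at large df", {
  # numeric CDF-inversion oracle
  oracle <- uniroot(function(q) pt(q, 1e6) - 0.975, c(1, 3), tol = 1e-10)$root
  expect_equal(critical_t(0.05, 1e6), oracle, tolerance = 1e-6)
  expect_equal(critical_t(0.05, 1e6), 1.960, tolerance = 1e-3)
  expect_error(critical_t(1.2, 10), "alpha")
  expect_error(critical_t(0.05, 0), "df")
})

test_that("permutation p-values equal exhaustive enumeration at n = 4", {
  set.seed(13)
  adj <- toy_adjacency_chain(3)
  a <- array(rnorm(4 * 3 * 5, 1.2), c(4, 3, 5))
  b <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  res <- cluster_permutation_test(a, b, adjacency = adj,
                                  config = cluster_config(t_crit = 2,
                                                          exhaustive = TRUE))
  want <- oracle_exhaustive_p(a - b, 2, adj)
  got <- vapply(res$clusters, `[[`, numeric(1), "p_value")
  # oracle reports in discovery order; compare as sorted sets paired by mass
  ord_got <- order(vapply(res$clusters, `[[`, numeric(1), "mass"))
  masses_o <- vapply(oracle_find_clusters(
    paired_tmap(a, b)$values, 2, adj), `[[`, numeric(1), "mass")
  ord_want <- order(masses_o)
  expect_equal(got[ord_got], want[ord_want], tolerance = 1e-12)
  expect_equal(length(res$null_distribution), 16)
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  set.seed(14)
  adj <- toy_adjacency_chain(3)
  a <- array(rnorm(4 * 3 * 5, 1.5), c(4, 3, 5))
  b <- array(rnorm(4 * 3 * 5), c(4, 3, 5))
  exact <- cluster_permutation_test(a, b, adjacency = adj,
                                    config = cluster_config(t_crit = 2,
                                                            exhaustive = TRUE))
  mc <- cluster_permutation_test(a, b, adjacency = adj,
                                 config = cluster_config(t_crit = 2,
                                                         n_perm = 4000,
                                                         seed = 99))
  p_exact <- exact$clusters[[1]]$p_value
  p_mc <- mc$clusters[[1]]$p_value
  expect_lt(abs(p_mc - p_exact), 0.03)
  # counting convention: smallest attainable Monte-Carlo p
  expect_gte(min(vapply(mc$clusters, `[[`, numeric(1), "p_value")),
             1 / (4000 + 1))
})

test_that("permutation test is deterministic under its seed", {
  set.seed(15)
  a <- array(rnorm(5 * 3 * 6, 1), c(5, 3, 6))
  b <- array(rnorm(5 * 3 * 6), c(5, 3, 6))
  adj <- toy_adjacency_chain(3)
  r1 <- cluster_permutation_test(a, b, adjacency = adj,
                                 config = cluster_config(t_crit = 2, n_perm = 100, seed = 7))
  r2 <- cluster_permutation_test(a, b, adjacency = adj,
                                 config = cluster_config(t_crit = 2, n_perm = 100, seed = 7))
  expect_identical(r1$null_distribution, r2$null_distribution)
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "p_value"),
                   vapply(r2$clusters, `[[`, numeric(1), "p_value"))
})
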