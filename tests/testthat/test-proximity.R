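cycle_graph <- function(n) {
  v <- paste0("V", seq_len(n))
  make_network(v, c(v[-1], v[1]), rep(1, n))
}

test_that("shortest distances are BFS hop counts with unreachable targets set aside", {
  st <- make_network(rep("C0", 4), paste0("L", 1:4), rep(1, 4))
  d <- shortest_distances(st, "C0", paste0("L", 1:4))
  expect_true(all(d$distances == 1))

  p <- make_network(c("A", "B"), c("B", "C"), c(1, 1))
  d2 <- shortest_distances(p, "A", c("B", "C"))
  expect_equal(d2$distances[c("B", "C")], c(B = 1, C = 2))

  disc <- make_network(c("A", "C"), c("B", "D"), c(1, 1))
  d3 <- shortest_distances(disc, "A", c("B", "C", "Z"))
  expect_equal(names(d3$distances), "B")
  expect_setequal(d3$unreachable, c("C", "Z"))
  expect_error(shortest_distances(p, "Q", "A"), "Q")
  # source excluded from targets by default, included on request
  d4 <- shortest_distances(p, "A", c("A", "B"))
  expect_false("A" %in% names(d4$distances))
  d5 <- shortest_distances(p, "A", c("A", "B"), include_source = TRUE)
  expect_equal(unname(d5$distances["A"]), 0)
})

test_that("observed proximity is the mean of finite distances", {
  expect_equal(observed_proximity(c(B = 1, C = 2)), 1.5)
  expect_equal(observed_proximity(c(1, 1, 1)), 1)
  expect_error(observed_proximity(numeric()), "unreachable")
})

test_that("permutation null on a 5-cycle matches the exact enumeration mean", {
  g <- cycle_graph(5)
  # exact: distances from any node are {1,1,2,2}; mean over all 2-subsets = 1.5
  d <- shortest_distances(g, "V1", paste0("V", 2:5))$distances
  subsets <- utils::combn(names(d), 2)
  exact <- mean(apply(subsets, 2, function(s) mean(d[s])))
  expect_equal(exact, 1.5)
  null <- permutation_null(g, "V1", set_size = 2, n_permutations = 4000, seed = 3)
  expect_equal(null$mu, 1.5, tolerance = 0.02)
})

test_that("permutation null is reproducible by seed and rejects degenerate nulls", {
  g <- random_connected_graph(10)
  n1 <- permutation_null(g, "A", 3, n_permutations = 200, seed = 42)
  n2 <- permutation_null(g, "A", 3, n_permutations = 200, seed = 42)
  expect_identical(n1$samples, n2$samples)
  n3 <- permutation_null(g, "A", 3, n_permutations = 200, seed = 43)
  expect_false(identical(n1$samples, n3$samples))

  pairs <- t(utils::combn(paste0("K", 1:5), 2))
  complete <- make_network(pairs[, 1], pairs[, 2], rep(1, nrow(pairs)))
  expect_error(permutation_null(complete, "K1", 2, 50, seed = 1), "degenerate")
})

test_that("null standard deviation uses the population convention", {
  g <- cycle_graph(6)
  null <- permutation_null(g, "V1", 2, n_permutations = 500, seed = 9)
  mu <- mean(null$samples)
  expect_equal(null$sigma, sqrt(mean((null$samples - mu)^2)), tolerance = 1e-12)
})

test_that("z and p follow the lower-tail standard normal convention", {
  zp <- proximity_z_p(1.5, 1.5, 0.2)
  expect_equal(zp$z, 0)
  expect_equal(zp$p, 0.5)
  zp2 <- proximity_z_p(1.5 - 0.009 * 0.3, 1.5, 0.3)
  expect_equal(zp2$z, -0.009, tolerance = 1e-12)
  expect_equal(round(zp2$p, 3), 0.496)
  zp3 <- proximity_z_p(-1.6449, 0, 1)
  expect_equal(zp3$p, 0.05, tolerance = 1e-4)
  expect_error(proximity_z_p(1, 1, 0), "sigma")
})

test_that("z is invariant to shifting all distances by a constant", {
  g <- random_connected_graph(12, p = 0.3)
  null <- permutation_null(g, "A", 4, 300, seed = 5)
  d_obs <- 1.7
  z1 <- proximity_z_p(d_obs, null$mu, null$sigma)$z
  shift <- 3.2
  z2 <- proximity_z_p(d_obs + shift, null$mu + shift, null$sigma)$z
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("direct neighbors intersect the core with optional self-inclusion", {
  st <- make_network(rep("C0", 4), paste0("L", 1:4), rep(1, 4))
  expect_setequal(direct_neighbors(st, "C0", paste0("L", 1:4)), paste0("L", 1:4))
  expect_length(direct_neighbors(st, "L1", c("L2", "L3")), 0)
  expect_true("C0" %in% direct_neighbors(st, "C0", c("C0", "L1")))
  expect_false("C0" %in% direct_neighbors(st, "C0", c("C0", "L1"),
                                          include_self = FALSE))
  expect_error(direct_neighbors(st, "ZZ", "L1"), "ZZ")
})

test_that("empirical-rank and normal-CDF p-values agree on a well-behaved null", {
  set.seed(8)
  g <- random_connected_graph(40, p = 0.12)
  src <- igraph::V(g)$name[1]
  core <- sample(igraph::V(g)$name[-1], 12)
  res <- proximity_test(g, src, core, n_permutations = 10000, seed = 11)
  null <- permutation_null(g, src, length(core), 10000, seed = 11)
  p_emp <- mean(null$samples <= res$observed_mean_distance)
  expect_lt(abs(p_emp - res$p), 0.05)
})

test_that("proximity_test is bit-identical across runs at a fixed seed", {
  g <- random_connected_graph(15, p = 0.25)
  core <- paste0(LETTERS[3:8])
  r1 <- proximity_test(g, "A", core, n_permutations = 500, seed = 77)
  r2 <- proximity_test(g, "A", core, n_permutations = 500, seed = 77)
  expect_identical(r1[setdiff(names(r1), "config")], r2[setdiff(names(r2), "config")])
})
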