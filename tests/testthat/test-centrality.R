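path_abc <- function() make_network(c("A", "B"), c("B", "C"), c(1, 1))
star5 <- function() make_network(rep("C0", 4), paste0("L", 1:4), rep(1, 4))
k4 <- function() {
  pairs <- t(utils::combn(c("A", "B", "C", "D"), 2))
  make_network(pairs[, 1], pairs[, 2], rep(1, 6))
}

test_that("degree centrality matches closed forms on complete, star and path graphs", {
  expect_true(all(degree_centrality(k4()) == 1))
  d <- degree_centrality(star5())
  expect_equal(unname(d["C0"]), 1)
  expect_true(all(d[paste0("L", 1:4)] == 0.25))
  p <- degree_centrality(path_abc())
  expect_equal(unname(p[c("A", "B", "C")]), c(0.5, 1, 0.5))
  expect_warning(degree_centrality(make_network(character(), character(),
                                                numeric(), nodes = "A")),
                 "single-node")
})

test_that("bipartite degree normalizes by the opposite partition", {
  sets <- list(s1 = c("G1", "G2"), s2 = c("G1", "G3"), s3 = "G1")
  net <- build_symptom_network(sets, mode = "bipartite")
  d <- degree_centrality(net, bipartite = TRUE)
  expect_equal(unname(d["G1"]), 1) # all 3 symptom terms
  expect_equal(unname(d["G2"]), 1 / 3)
  expect_equal(unname(d["s1"]), 2 / 3) # term node over 3 genes
})

test_that("betweenness matches closed forms and is zero for tiny graphs", {
  b <- betweenness_centrality(path_abc())
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  expect_true(all(betweenness_centrality(k4()) == 0))
  two <- make_network("A", "B", 1)
  expect_true(all(betweenness_centrality(two) == 0))
})

test_that("closeness follows the Wasserman-Faust convention on connected and disconnected graphs", {
  expect_equal(unname(closeness_centrality(star5())["C0"]), 1)
  expect_equal(unname(closeness_centrality(path_abc())["A"]), 2 / 3)
  # two disjoint edges: each node (1/1) * (1/3)
  dis <- make_network(c("A", "C"), c("B", "D"), c(1, 1))
  expect_equal(unname(closeness_centrality(dis)), rep(1 / 3, 4))
  # isolated node scores zero
  iso <- make_network("A", "B", 1, nodes = "X")
  expect_equal(unname(closeness_centrality(iso)["X"]), 0)
})

test_that("eigenvector centrality matches closed forms; edge variant responds to confidences", {
  cyc <- make_network(c("A", "B", "C", "D"), c("B", "C", "D", "A"), rep(1, 4))
  expect_equal(unname(eigenvector_centrality(cyc, "linked")), rep(0.5, 4),
               tolerance = 1e-8)
  ev <- eigenvector_centrality(star5(), "linked")
  expect_equal(unname(ev["C0"] / ev["L1"]), 2, tolerance = 1e-8) # sqrt(4)
  wp <- make_network(c("A", "B"), c("B", "C"), c(1, 0.5))
  lin <- eigenvector_centrality(wp, "linked")
  edg <- eigenvector_centrality(wp, "edge")
  expect_equal(unname(lin["A"]), unname(lin["C"]), tolerance = 1e-8)
  expect_gt(edg["A"], edg["C"])
  # against a small dense eigen-decomposition
  expect_equal(unname(edg), unname(oracle_eigenvector(wp, weighted = TRUE)),
               tolerance = 1e-7)
})

test_that("all five centralities agree with brute-force oracles on random connected graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    g <- random_connected_graph(n)
    expect_equal(degree_centrality(g), oracle_degree(g), tolerance = 1e-12)
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-10)
    expect_equal(closeness_centrality(g), oracle_closeness(g),
                 tolerance = 1e-12)
    expect_equal(eigenvector_centrality(g, "linked"), oracle_eigenvector(g),
                 tolerance = 1e-7)
    expect_equal(eigenvector_centrality(g, "edge"),
                 oracle_eigenvector(g, weighted = TRUE), tolerance = 1e-7)
  }
})

test_that("centrality scores are invariant under node relabeling", {
  set.seed(7)
  g <- random_connected_graph(7)
  perm <- sample(7)
  relabeled <- g
  igraph::V(relabeled)$name <- paste0("X", perm)
  tab1 <- centrality_table(g)
  tab2 <- centrality_table(relabeled)
  tab2 <- tab2[match(paste0("X", perm), tab2$gene), ]
  for (m in centrality_metrics()) {
    expect_equal(tab2[[m]], tab1[[m]], tolerance = 1e-8)
  }
})

test_that("scores respect their bounds and eigenvector vectors are unit-norm per component", {
  set.seed(99)
  for (rep in 1:10) {
    g <- random_connected_graph(sample(3:8, 1))
    tab <- centrality_table(g)
    for (m in c("degree", "betweenness", "closeness")) {
      expect_true(all(tab[[m]] >= 0 & tab[[m]] <= 1))
    }
    expect_equal(sum(tab$eigenvector_linked^2), 1, tolerance = 1e-8)
    expect_equal(sum(tab$eigenvector_edge^2), 1, tolerance = 1e-8)
    # ranks are a permutation of 1..N under competition ranking
    r <- tab$degree_rank
    expect_true(all(sort(unique(r)) %in% seq_len(nrow(tab))))
    expect_equal(min(r), 1)
  }
})

test_that("competition ranks share the minimum rank on ties", {
  r <- competition_rank(c(a = 3, b = 5, c = 5, d = 1))
  expect_equal(unname(r[c("b", "c")]), c(1L, 1L))
  expect_equal(unname(r["a"]), 3L)
  expect_equal(unname(r["d"]), 4L)
})
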