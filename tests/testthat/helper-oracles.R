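# Independent brute-force oracles used to cross-check the package's
# centrality, multiplicity, FDR and enrichment computations. Everything here
# works from plain matrices and enumeration, never through the code paths
# under test.

adjacency_of <- function(net, weighted = FALSE) {
  v <- igraph::V(net)$name
  a <- matrix(0, length(v), length(v), dimnames = list(v, v))
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el)) {
    w <- if (weighted) igraph::E(net)$confidence else rep(1, nrow(el))
    for (i in seq_len(nrow(el))) {
      a[el[i, 1], el[i, 2]] <- w[i]
      a[el[i, 2], el[i, 1]] <- w[i]
    }
  }
  a
}

# hop distances and shortest-path counts from powers of the binary
# adjacency: a length-L walk realizing the shortest distance is necessarily
# a shortest path, so sigma(s,t) = (A^d)[s,t]
oracle_paths <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(d) <- 0
  diag(sigma) <- 1
  pw <- diag(n)
  for (L in seq_len(n)) {
    pw <- pw %*% a
    new <- is.infinite(d) & pw > 0
    d[new] <- L
    sigma[new] <- pw[new]
  }
  list(d = d, sigma = sigma)
}

oracle_degree <- function(net) {
  a <- adjacency_of(net)
  rowSums(a > 0) / (nrow(a) - 1)
}

oracle_betweenness <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  op <- oracle_paths(a)
  bw <- stats::setNames(rep(0, n), rownames(a))
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || !is.finite(op$d[s, t])) next
        if (op$d[s, v] + op$d[v, t] == op$d[s, t]) {
          bw[v] <- bw[v] + op$sigma[s, v] * op$sigma[v, t] / op$sigma[s, t]
        }
      }
    }
  }
  bw / ((n - 1) * (n - 2) / 2)
}

oracle_closeness <- function(net) {
  a <- adjacency_of(net)
  n <- nrow(a)
  d <- oracle_paths(a)$d
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    if (!length(fin)) return(0)
    (length(fin) / sum(fin)) * (length(fin) / (n - 1))
  }, numeric(1)) |> stats::setNames(rownames(a))
}

oracle_eigenvector <- function(net, weighted = FALSE) {
  a <- adjacency_of(net, weighted = weighted)
  comp <- igraph::components(net)$membership
  out <- stats::setNames(rep(0, nrow(a)), rownames(a))
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) == 1) next
    ev <- eigen(a[idx, idx], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    out[idx] <- v / sqrt(sum(v^2))
  }
  out
}

# O(m^2) rank-by-rank Benjamini-Hochberg, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    adj_sorted[i] <- min(1, min(candidates))
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# exhaustive hypergeometric upper tail by enumerating every size-n draw
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(dr) sum(dr <= K) >= k)
  mean(hits)
}

# build a pathway_collection through the public GMT interface
make_pathway_collection_test <- function(pathways, universe = NULL) {
  f <- tempfile(fileext = ".gmt")
  on.exit(unlink(f))
  writeLines(vapply(names(pathways), function(nm) {
    paste(c(nm, "test set", pathways[[nm]]), collapse = "\t")
  }, character(1)), f)
  read_gmt(f, universe = universe)
}

# random connected graph on n nodes (letters as names)
random_connected_graph <- function(n, p = 0.45) {
  repeat {
    full <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(full)) < p
    if (!any(keep)) next
    g <- igraph::graph_from_edgelist(full[keep, , drop = FALSE], directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- if (n <= 26) LETTERS[seq_len(n)] else
        sprintf("V%03d", seq_len(n))
      igraph::E(g)$confidence <- round(stats::runif(igraph::ecount(g), 0.4, 1), 3)
      return(g)
    }
  }
}
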