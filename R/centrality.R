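#' Freeman-normalized degree centrality
#'
#' Degree divided by `N - 1` where `N` is the node count. In bipartite mode
#' each node's degree is divided by the size of the opposite partition
#' instead, which is the natural normalization for a gene-symptom two-mode
#' network (a gene touching all `m` symptom terms scores 1).
#'
#' @param net an `igraph` network.
#' @param bipartite logical; if `TRUE`, `net` must carry a logical vertex
#'   attribute `type` marking the two partitions.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
degree_centrality <- function(net, bipartite = FALSE) {
  n <- igraph::vcount(net)
  stopifnot(n > 0)
  deg <- igraph::degree(net)
  if (bipartite) {
    type <- igraph::vertex_attr(net, "type")
    if (is.null(type)) stop("bipartite mode requires a logical 'type' vertex attribute")
    opp <- ifelse(type, sum(!type), sum(type))
    return(stats::setNames(ifelse(opp > 0, deg / opp, 0), igraph::V(net)$name))
  }
  if (n == 1) {
    warning("single-node network: degree centrality is zero")
    return(stats::setNames(0, igraph::V(net)$name))
  }
  deg / (n - 1)
}

#' Normalized shortest-path betweenness centrality
#'
#' Exact (Brandes) unweighted betweenness, normalized by `(N-1)(N-2)/2` so a
#' path's middle node scores 1. Edge confidences are ignored for path
#' finding: paths are hop counts, confidences act only as inclusion filters.
#'
#' @param net an `igraph` network.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  stopifnot(n > 0)
  if (n < 3) {
    return(stats::setNames(rep(0, n), igraph::V(net)$name))
  }
  igraph::betweenness(net, directed = FALSE, weights = NA, normalized = TRUE)
}

#' Wasserman-Faust closeness centrality
#'
#' For each node, `(r - 1) / sum(d)` over the `r` reachable nodes (including
#' itself), multiplied by `(r - 1) / (N - 1)` so that scores of nodes in
#' small components are damped on disconnected graphs. Isolated nodes score
#' 0. Distances are unweighted hop counts.
#'
#' @param net an `igraph` network.
#' @return named numeric vector of scores in `[0, 1]`.
#' @export
closeness_centrality <- function(net) {
  n <- igraph::vcount(net)
  stopifnot(n > 0)
  if (n == 1) return(stats::setNames(0, igraph::V(net)$name))
  d <- igraph::distances(net, weights = NA)
  scores <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    r1 <- length(fin) # reachable minus one (self excluded)
    if (r1 == 0) return(0)
    (r1 / sum(fin)) * (r1 / (n - 1))
  }, numeric(1))
  stats::setNames(scores, igraph::V(net)$name)
}

#' Eigenvector centrality (binary or confidence-weighted)
#'
#' Principal-eigenvector scores computed per connected component by shifted
#' power iteration (iterating `(A + I) x`, which preserves the principal
#' eigenvector and converges on bipartite components), Euclidean-normalized
#' within each component. Variant `"linked"` uses the binary adjacency;
#' variant `"edge"` weights the adjacency by edge confidence. Isolated nodes
#' score 0.
#'
#' @param net an `igraph` network.
#' @param variant `"linked"` (binary adjacency) or `"edge"`
#'   (confidence-weighted adjacency).
#' @param tol convergence tolerance on the score vector (max absolute change).
#' @param max_iter maximum power-iteration sweeps.
#' @return named numeric vector; Euclidean norm 1 within each component with
#'   at least one edge.
#' @export
eigenvector_centrality <- function(net, variant = c("linked", "edge"),
                                   tol = 1e-10, max_iter = 10000L) {
  variant <- match.arg(variant)
  n <- igraph::vcount(net)
  stopifnot(n > 0)
  w <- if (variant == "edge") network_confidence(net) else rep(1, igraph::ecount(net))
  adj <- igraph::as_adjacency_matrix(net, attr = NULL, sparse = TRUE)
  if (variant == "edge" && igraph::ecount(net) > 0) {
    igraph::E(net)$pi_weight <- w
    adj <- igraph::as_adjacency_matrix(net, attr = "pi_weight", sparse = TRUE)
  }
  comp <- igraph::components(net)
  scores <- stats::setNames(rep(0, n), igraph::V(net)$name)
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    if (length(idx) == 1) next # isolated node: no influence
    a <- adj[idx, idx, drop = FALSE]
    x <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      y <- as.numeric(a %*% x) + x # (A + I) x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol) {
        x <- y
        converged <- TRUE
        break
      }
      x <- y
    }
    if (!converged) {
      stop(sprintf("eigenvector centrality did not converge within %d iterations", max_iter))
    }
    scores[idx] <- x
  }
  scores
}

#' Competition ranks for centrality scores
#'
#' Rank 1 is the highest score; ties share the minimum rank.
#'
#' @param scores named numeric vector.
#' @return named integer vector of ranks.
#' @export
competition_rank <- function(scores) {
  r <- rank(-scores, ties.method = "min")
  stats::setNames(as.integer(r), names(scores))
}

#' Five-metric centrality table
#'
#' Computes all five node-centrality indices used by the pipeline (degree,
#' betweenness, closeness, eigenvector on the binary adjacency, eigenvector
#' on the confidence-weighted adjacency) with competition ranks per metric.
#'
#' @param net an `igraph` network.
#' @param bipartite passed to [degree_centrality()].
#' @return a `data.frame` with one row per gene: `gene`, then
#'   `<metric>` score and `<metric>_rank` columns for the five metrics.
#' @export
centrality_table <- function(net, bipartite = FALSE) {
  cols <- list(
    degree = degree_centrality(net, bipartite = bipartite),
    betweenness = betweenness_centrality(net),
    closeness = closeness_centrality(net),
    eigenvector_linked = eigenvector_centrality(net, "linked"),
    eigenvector_edge = eigenvector_centrality(net, "edge")
  )
  out <- data.frame(gene = igraph::V(net)$name, stringsAsFactors = FALSE)
  for (nm in names(cols)) {
    sc <- cols[[nm]][out$gene]
    out[[nm]] <- as.numeric(sc)
    out[[paste0(nm, "_rank")]] <- as.integer(competition_rank(sc))
  }
  rownames(out) <- NULL
  out
}

#' Metric names of the five-centrality consensus
#' @return character vector of the five metric column names used by
#'   [centrality_table()].
#' @export
centrality_metrics <- function() {
  c("degree", "betweenness", "closeness", "eigenvector_linked", "eigenvector_edge")
}
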