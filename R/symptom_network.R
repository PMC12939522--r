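#' Build a symptom-association network from filtered gene sets
#'
#' Two constructions are supported for the network on which gene
#' centralities are scored. The bipartite mode (default) links each gene to
#' every symptom term whose filtered set contains it; with the two-mode
#' degree normalization, a gene attached to all `m` symptom terms has degree
#' score 1 and scores are quantized in steps of `1/m`. The projection mode
#' links two genes whenever they share at least one symptom term, with the
#' shared-term count kept as an edge attribute.
#'
#' @param collection named list of character vectors (filtered gene sets per
#'   symptom term, e.g. from [filter_by_relevance()]).
#' @param mode `"bipartite"` or `"projection"`.
#' @return an `igraph`; in bipartite mode with a logical `type` vertex
#'   attribute (`TRUE` for symptom-term nodes).
#' @export
build_symptom_network <- function(collection, mode = c("bipartite", "projection")) {
  mode <- match.arg(mode)
  stopifnot(length(collection) >= 1, !is.null(names(collection)))
  genes <- union_merge(collection)
  terms <- names(collection)
  clash <- intersect(genes, terms)
  if (length(clash)) {
    stop("symptom term label(s) clash with gene symbols: ",
         paste(clash, collapse = ", "))
  }
  if (mode == "bipartite") {
    from <- rep(terms, lengths(collection))
    to <- unlist(collection, use.names = FALSE)
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(genes), name = genes, type = FALSE)
    g <- igraph::add_vertices(g, length(terms), name = terms, type = TRUE)
    if (length(from)) {
      g <- igraph::add_edges(g, rbind(from, to), confidence = 1)
    }
    g <- igraph::simplify(g, edge.attr.comb = "max")
    return(g)
  }
  m <- membership_matrix(collection)
  shared <- m %*% t(m) # gene x gene shared-term counts
  adj <- shared
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  ij <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ij)) {
    igraph::E(g)$shared_terms <- shared[cbind(ij[, 1], ij[, 2])]
    igraph::E(g)$confidence <- 1
  }
  g
}

#' Gene-side centrality table for a symptom network
#'
#' Runs [centrality_table()] on a symptom-association network and restricts
#' the scored rows to gene nodes (two-mode networks also rank only genes,
#' with the opposite-partition degree normalization).
#'
#' @param net an `igraph` from [build_symptom_network()].
#' @return a `data.frame` as from [centrality_table()], genes only, with
#'   ranks recomputed over genes.
#' @export
symptom_centrality <- function(net) {
  type <- igraph::vertex_attr(net, "type")
  bipartite <- !is.null(type)
  tab <- centrality_table(net, bipartite = bipartite)
  if (bipartite) {
    tab <- tab[!type[match(tab$gene, igraph::V(net)$name)], , drop = FALSE]
    for (m in centrality_metrics()) {
      tab[[paste0(m, "_rank")]] <-
        as.integer(competition_rank(stats::setNames(tab[[m]], tab$gene)))
    }
    rownames(tab) <- NULL
  }
  tab
}
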