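#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. No alias or HGNC resolution
#' is attempted; symbols are treated as opaque identifiers.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Build a confidence-scored interaction network
#'
#' Constructs an undirected [igraph::igraph] with a `confidence` edge
#' attribute in `[0, 1]`. Self-loops are dropped, duplicate edges (in either
#' orientation) are collapsed keeping the maximum confidence, and node symbols
#' are normalized with [normalize_symbols()].
#'
#' @param from,to character vectors of endpoint gene symbols.
#' @param confidence numeric vector of edge confidences in `[0, 1]`.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to register.
#' @return an undirected `igraph` object with edge attribute `confidence`.
#' @export
make_network <- function(from, to, confidence = rep(1, length(from)),
                         nodes = character()) {
  stopifnot(length(from) == length(to), length(from) == length(confidence))
  from <- normalize_symbols(from)
  to <- normalize_symbols(to)
  confidence <- as.numeric(confidence)
  if (any(!is.finite(confidence)) || any(confidence < 0 | confidence > 1)) {
    stop("edge confidences must be finite and within [0, 1]")
  }
  keep <- from != to
  from <- from[keep]; to <- to[keep]; confidence <- confidence[keep]
  # collapse duplicates (unordered) keeping the maximum confidence
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\t")
  if (anyDuplicated(key)) {
    confidence <- tapply(confidence, key, max)
    parts <- strsplit(names(confidence), "\t", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    confidence <- as.numeric(confidence)
  }
  verts <- sort(unique(c(a, b, normalize_symbols(nodes))))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(a, b), confidence = confidence)
  }
  g
}

#' Read a confidence-filtered edge list
#'
#' Reads a tab-separated edge list (`protein1  protein2  combined_score`,
#' header optional) and returns the network of edges whose confidence is at
#' least `min_confidence`. Scores are accepted on either a 0-1 or 0-1000
#' scale; any score greater than 1 triggers division of all scores by 1000,
#' matching STRING export dialects. Symbols are uppercased and stripped,
#' duplicate rows are collapsed keeping the maximum confidence, and nodes
#' appearing only in dropped edges are excluded.
#'
#' @param path path to a tab-separated file with at least three columns.
#' @param min_confidence minimum edge confidence in `[0, 1]` (inclusive).
#' @return an undirected `igraph` with edge attribute `confidence`.
#' @export
read_edge_list <- function(path, min_confidence = 0.7) {
  stopifnot(is.numeric(min_confidence), length(min_confidence) == 1,
            min_confidence >= 0, min_confidence <= 1)
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  if (!length(lines_keep)) {
    return(make_network(character(), character(), numeric()))
  }
  first <- strsplit(lines[lines_keep[1]], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) lines_keep <- lines_keep[-1]
  if (!length(lines_keep)) {
    return(make_network(character(), character(), numeric()))
  }
  from <- to <- character(length(lines_keep))
  score <- numeric(length(lines_keep))
  for (i in seq_along(lines_keep)) {
    ln <- lines_keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed edge-list row at line %d: expected 3 columns, got %d",
                   ln, length(fields)))
    }
    s <- suppressWarnings(as.numeric(fields[3]))
    if (is.na(s)) {
      stop(sprintf("malformed edge-list row at line %d: non-numeric score '%s'",
                   ln, fields[3]))
    }
    from[i] <- fields[1]; to[i] <- fields[2]; score[i] <- s
  }
  if (any(score > 1)) score <- score / 1000
  keep <- score >= min_confidence
  make_network(from[keep], to[keep], score[keep])
}

#' Write a network as a tab-separated edge list
#'
#' Emits the `protein1  protein2  combined_score` dialect consumed by
#' [read_edge_list()], plus (optionally) a node-list file so isolated nodes
#' survive a round trip.
#'
#' @param net an `igraph` network with a `confidence` edge attribute.
#' @param path output path for the edge list.
#' @param node_path optional output path for the one-symbol-per-line node list.
#' @param header write the column header line?
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, node_path = NULL, header = TRUE) {
  el <- igraph::as_edgelist(net, names = TRUE)
  conf <- network_confidence(net)
  out <- character()
  if (header) out <- "protein1\tprotein2\tcombined_score"
  if (nrow(el)) {
    out <- c(out, sprintf("%s\t%s\t%s", el[, 1], el[, 2],
                          formatC(conf, format = "fg", digits = 15)))
  }
  writeLines(out, path)
  if (!is.null(node_path)) {
    writeLines(sort(igraph::V(net)$name), node_path)
  }
  invisible(path)
}

network_confidence <- function(net) {
  conf <- igraph::edge_attr(net, "confidence")
  if (is.null(conf)) conf <- rep(1, igraph::ecount(net))
  conf
}

#' Restrict a network to a gene set and drop unconnected nodes
#'
#' Induces the subgraph on `keep` and then removes every node with zero edges
#' in that subgraph, mirroring the exclusion of low-confidence or
#' disconnected nodes during core-set refinement.
#'
#' @param net an `igraph` network.
#' @param keep character vector of gene symbols to retain (defaults to all).
#' @return the induced `igraph` with isolated nodes removed.
#' @export
drop_unconnected <- function(net, keep = igraph::V(net)$name) {
  keep <- intersect(normalize_symbols(keep), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, keep)
  igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
}
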