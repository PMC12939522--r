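#' Read a GMT gene-set file
#'
#' Standard GMT dialect: tab-separated lines of set name, description, then
#' member gene symbols. Symbols are normalized and deduplicated within each
#' set. The universe defaults to the union of all pathway members unless
#' supplied.
#'
#' @param path path to a GMT file.
#' @param universe optional character vector overriding the gene universe.
#' @return a `pathway_collection`: list with `pathways` (named list of
#'   character vectors), `descriptions` (named character), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pathways <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    }
    nm <- fields[1]
    pathways[[nm]] <- sort(unique(normalize_symbols(fields[-(1:2)])))
    descriptions[nm] <- fields[2]
  }
  make_pathway_collection(pathways, descriptions, universe)
}

make_pathway_collection <- function(pathways, descriptions = NULL, universe = NULL) {
  if (is.null(universe)) {
    universe <- sort(unique(unlist(pathways, use.names = FALSE)))
  } else {
    universe <- sort(unique(normalize_symbols(universe)))
    pathways <- lapply(pathways, intersect, universe)
    empty <- names(pathways)[lengths(pathways) == 0]
    if (length(empty)) {
      message("pathway(s) empty after universe restriction, dropped: ",
              paste(empty, collapse = ", "))
      pathways <- pathways[lengths(pathways) > 0]
    }
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(pathways)), names(pathways))
  }
  structure(list(pathways = pathways,
                 descriptions = descriptions[names(pathways)],
                 universe = universe),
            class = "pathway_collection")
}

#' Write a pathway collection as GMT
#'
#' @param collection a `pathway_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$pathways), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$pathways[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("Pathway collection: %d gene sets over a %d-gene universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Refined gene set: target neighbors plus top-decile central core genes
#'
#' Builds the focused gene set used for pathway analysis by merging the
#' direct-neighbor list of a drug target with the top fraction (default top
#' 10 percent) of the core genes ranked by a centrality score, deduplicated.
#'
#' @param target_neighbors character vector (e.g. from [direct_neighbors()]).
#' @param centrality named numeric vector of centrality scores covering the
#'   core genes.
#' @param core character vector, the core gene set ranked within.
#' @param decile top fraction of the core to keep (default 0.10).
#' @return sorted character vector, the union.
#' @export
refined_gene_set <- function(target_neighbors, centrality, core, decile = 0.10) {
  stopifnot(decile > 0, decile <= 1, length(core) >= 1)
  core <- unique(normalize_symbols(core))
  sc <- centrality[intersect(core, names(centrality))]
  if (!length(sc)) stop("no centrality scores available for the core genes")
  central <- top_fraction(sc, fraction = decile)
  sort(union(unique(normalize_symbols(target_neighbors)), central))
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the realized overlap between the query set and the pathway
#' within the universe, with BH FDR across tested pathways. Query genes
#' outside the universe are dropped with a message.
#'
#' @param query character vector of gene symbols.
#' @param pathways a `pathway_collection`.
#' @return a `data.frame` sorted by p: `pathway`, `overlap` (k), `pathway_size`
#'   (K), `query_size` (n), `universe_size` (N), `p_hypergeometric`, `p_fdr`,
#'   `neg_log10_p`, `genes` (semicolon-joined overlap).
#' @export
ora_hypergeometric <- function(query, pathways) {
  stopifnot(inherits(pathways, "pathway_collection"))
  query <- unique(normalize_symbols(query))
  dropped <- setdiff(query, pathways$universe)
  if (length(dropped)) {
    message(length(dropped), " query gene(s) outside the universe dropped: ",
            paste(dropped, collapse = ", "))
  }
  query <- intersect(query, pathways$universe)
  if (!length(query)) stop("no query genes left within the universe")
  N <- length(pathways$universe)
  n <- length(query)
  rows <- lapply(names(pathways$pathways), function(nm) {
    members <- pathways$pathways[[nm]]
    k <- length(intersect(query, members))
    K <- length(members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, overlap = k, pathway_size = K, query_size = n,
               universe_size = N, p_hypergeometric = p,
               genes = paste(intersect(query, members), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_fdr(res$p_hypergeometric)
  res$neg_log10_p <- -log10(res$p_hypergeometric)
  res <- res[order(res$p_hypergeometric, res$pathway),
             c("pathway", "overlap", "pathway_size", "query_size",
               "universe_size", "p_hypergeometric", "p_fdr", "neg_log10_p",
               "genes")]
  rownames(res) <- NULL
  res
}
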