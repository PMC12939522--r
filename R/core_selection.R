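#' Tie-aware top-fraction selection
#'
#' Returns the `ceiling(fraction * N)` highest-scoring genes, extended to
#' include every gene tied with the cutoff score (competition-rank
#' inclusion), so selection is deterministic under ties. An exclusive tie
#' policy is available for comparison.
#'
#' @param scores named numeric vector, one score per gene.
#' @param fraction fraction in `(0, 1]` (default 0.05, the top 5 percent).
#' @param ties `"include"` (default) extends past the cutoff to cover all
#'   tied genes; `"exclude"` drops the whole tied block if it straddles the
#'   cutoff.
#' @return character vector of selected genes.
#' @export
top_fraction <- function(scores, fraction = 0.05, ties = c("include", "exclude")) {
  ties <- match.arg(ties)
  if (!length(scores)) stop("empty score map")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  n_top <- ceiling(fraction * length(scores))
  ord <- order(scores, decreasing = TRUE)
  cutoff <- scores[ord[n_top]]
  if (ties == "include") {
    sel <- names(scores)[scores >= cutoff]
  } else {
    strict <- names(scores)[scores > cutoff]
    sel <- if (sum(scores == cutoff) + length(strict) == n_top) {
      names(scores)[scores >= cutoff]
    } else {
      strict
    }
  }
  sel
}

#' Consensus core across centrality metrics
#'
#' Genes appearing in at least `min_metrics` of the per-metric top sets.
#' With five metrics, `min_metrics = 5` gives the strict all-metric
#' consensus; `min_metrics = 1` gives the union.
#'
#' @param per_metric_top named list of character vectors (top genes per
#'   metric).
#' @param min_metrics integer in `1..length(per_metric_top)`.
#' @return sorted character vector of consensus genes.
#' @export
consensus_core <- function(per_metric_top, min_metrics = length(per_metric_top)) {
  k <- length(per_metric_top)
  stopifnot(k >= 1, min_metrics >= 1, min_metrics <= k)
  mc <- membership_counts(per_metric_top)
  sort(names(mc$counts)[mc$counts >= min_metrics])
}

#' PPI-based refinement of a candidate core
#'
#' Removes candidates absent from the (already confidence-filtered) PPI
#' network, then candidates with zero edges within the candidate-induced
#' subgraph, logging every removal with its reason. A whole-network degree
#' criterion is available via `connectivity`.
#'
#' @param candidate character vector of candidate genes.
#' @param ppi an `igraph` PPI network, already confidence-filtered.
#' @param connectivity `"induced"` (default; zero edges within the
#'   candidate-induced subgraph removes a gene) or `"global"` (zero edges in
#'   the whole network).
#' @return an object of class `consensus_core`: list with `candidate`,
#'   `refined`, and `removed` (data.frame of gene/reason).
#' @export
ppi_refine <- function(candidate, ppi, connectivity = c("induced", "global")) {
  connectivity <- match.arg(connectivity)
  candidate <- sort(unique(normalize_symbols(candidate)))
  present <- candidate %in% igraph::V(ppi)$name
  removed <- data.frame(gene = candidate[!present],
                        reason = rep("not in PPI", sum(!present)),
                        stringsAsFactors = FALSE)
  inppi <- candidate[present]
  if (length(inppi)) {
    deg <- if (connectivity == "induced") {
      igraph::degree(igraph::induced_subgraph(ppi, inppi))
    } else {
      igraph::degree(ppi, v = inppi)
    }
    iso <- inppi[deg[inppi] == 0]
    if (length(iso)) {
      removed <- rbind(removed, data.frame(gene = iso,
                                           reason = rep("disconnected", length(iso)),
                                           stringsAsFactors = FALSE))
    }
    refined <- setdiff(inppi, iso)
  } else {
    refined <- character()
  }
  removed <- removed[order(removed$gene), , drop = FALSE]
  rownames(removed) <- NULL
  structure(list(candidate = candidate, refined = sort(refined),
                 removed = removed),
            class = "consensus_core")
}

#' @export
print.consensus_core <- function(x, ...) {
  cat("Consensus core refinement\n")
  cat(sprintf("  candidates: %d\n  refined:    %d\n  removed:    %d\n",
              length(x$candidate), length(x$refined), nrow(x$removed)))
  if (nrow(x$removed)) {
    for (r in unique(x$removed$reason)) {
      cat(sprintf("    %s: %s\n", r,
                  paste(x$removed$gene[x$removed$reason == r], collapse = ", ")))
    }
  }
  invisible(x)
}
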