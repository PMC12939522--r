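#' Read gene-symptom relevance tables
#'
#' Accepts either a single three-column table (`gene  symptom
#' relevance_score`, header optional) or several two-column per-symptom
#' tables (`gene  relevance_score`), in which case the symptom term is
#' inferred from each file name. Duplicate (gene, symptom) pairs keep the
#' maximum score; symbols are normalized.
#'
#' @param paths one or more file paths.
#' @return a `data.frame` with columns `gene`, `symptom`, `relevance`.
#' @export
read_symptom_tables <- function(paths) {
  pieces <- lapply(paths, function(p) {
    df <- utils::read.delim(p, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!nrow(df)) return(NULL)
    # drop header row if last column is non-numeric
    last <- df[[ncol(df)]]
    if (is.na(suppressWarnings(as.numeric(last[1])))) df <- df[-1, , drop = FALSE]
    if (!nrow(df)) return(NULL)
    if (ncol(df) >= 3) {
      out <- data.frame(gene = df[[1]], symptom = df[[2]],
                        relevance = suppressWarnings(as.numeric(df[[3]])),
                        stringsAsFactors = FALSE)
    } else if (ncol(df) == 2) {
      symptom <- sub("\\.[^.]*$", "", basename(p))
      out <- data.frame(gene = df[[1]], symptom = symptom,
                        relevance = suppressWarnings(as.numeric(df[[2]])),
                        stringsAsFactors = FALSE)
    } else {
      stop(sprintf("symptom table '%s' must have 2 or 3 columns", p))
    }
    bad <- which(is.na(out$relevance))
    if (length(bad)) {
      stop(sprintf("non-numeric relevance score in '%s' (row %d)", p, bad[1]))
    }
    out
  })
  tab <- do.call(rbind, pieces)
  if (is.null(tab)) {
    return(data.frame(gene = character(), symptom = character(),
                      relevance = numeric(), stringsAsFactors = FALSE))
  }
  tab$gene <- normalize_symbols(tab$gene)
  if (any(tab$relevance < 0)) stop("relevance scores must be nonnegative")
  # keep max score per (gene, symptom)
  o <- order(tab$gene, tab$symptom, -tab$relevance)
  tab <- tab[o, , drop = FALSE]
  tab <- tab[!duplicated(tab[c("gene", "symptom")]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Relevance-threshold filtering per symptom
#'
#' For each symptom term, returns the set of genes whose relevance score is
#' at least `threshold` (inclusive, matching a relevance-score cutoff of
#' ">= 20"). Symptoms whose every gene falls below the threshold are
#' retained as empty sets, with a message.
#'
#' @param table a `data.frame` as returned by [read_symptom_tables()].
#' @param threshold nonnegative relevance cutoff (default 20).
#' @return named list of character vectors, one per symptom term.
#' @export
filter_by_relevance <- function(table, threshold = 20) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single nonnegative number")
  }
  symptoms <- unique(table$symptom)
  sets <- lapply(symptoms, function(s) {
    sub <- table[table$symptom == s & table$relevance >= threshold, , drop = FALSE]
    sort(unique(sub$gene))
  })
  names(sets) <- symptoms
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    message("symptom term(s) with no gene at threshold ", threshold, ": ",
            paste(empty, collapse = ", "))
  }
  sets
}

#' Union merge of a gene-set collection
#'
#' The union-based merging strategy preserves symptom-specific molecular
#' diversity rather than collapsing to an intersection.
#'
#' @param collection named list of character vectors.
#' @return sorted character vector, the union of all member sets.
#' @export
union_merge <- function(collection) {
  sort(unique(unlist(collection, use.names = FALSE)))
}

#' Multi-list membership (Venn) accounting
#'
#' Counts, per gene, how many member sets contain it, and summarizes the
#' number of genes contained in at least `k` sets for `k = 1..K`.
#'
#' @param collection named list of character vectors.
#' @return a list with `counts` (named integer vector, per gene) and
#'   `at_least` (integer vector indexed by `k`).
#' @export
membership_counts <- function(collection) {
  stopifnot(length(collection) >= 1)
  k <- length(collection)
  tab <- table(unlist(lapply(collection, unique), use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  at_least <- vapply(seq_len(k), function(m) sum(counts >= m), integer(1))
  names(at_least) <- paste0(">=", seq_len(k))
  list(counts = counts, at_least = at_least)
}

#' Sorted set intersection
#'
#' @param a,b character vectors of gene symbols.
#' @return sorted character vector `a` \eqn{\cap} `b`.
#' @export
intersect_sets <- function(a, b) {
  sort(intersect(unique(a), unique(b)))
}

#' Gene-by-set membership matrix
#'
#' @param collection named list of character vectors.
#' @return a logical matrix, genes in rows (sorted), sets in columns.
#' @export
membership_matrix <- function(collection) {
  genes <- union_merge(collection)
  m <- vapply(collection, function(s) genes %in% s, logical(length(genes)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(genes))
  rownames(m) <- genes
  colnames(m) <- names(collection)
  m
}
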