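#' Load a case-control expression study
#'
#' Reads either a GEO SOFT file in the curated-dataset (GDS) dialect —
#' a `!dataset_table_begin` block with `ID_REF`/`IDENTIFIER` columns and
#' `^SUBSET` sections carrying "disease state" sample groups — or a plain
#' TSV matrix accompanied by a two-column sample/group label file. Probes
#' with any non-numeric value are dropped with a message. The value scale is
#' auto-detected unless given: intensities that include negative values and
#' never exceed ~30 are treated as log2 and exponentiated before any fold
#' change is computed.
#'
#' @param path path to the SOFT or matrix file.
#' @param format `"soft"` or `"matrix_tsv"`.
#' @param labels for `matrix_tsv`, path to a tab-separated `sample  group`
#'   file (groups `case`/`control`).
#' @param scale `"auto"`, `"linear"` or `"log2"`.
#' @return object of class `expression_study`: list with `matrix` (probes x
#'   samples), `groups` (named factor, levels `control`, `case`),
#'   `probe_map` (probe -> gene symbol), `scale`.
#' @export
load_expression <- function(path, format = c("soft", "matrix_tsv"),
                            labels = NULL, scale = c("auto", "linear", "log2")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (format == "soft") {
    study <- parse_soft_gds(path)
  } else {
    if (is.null(labels)) stop("matrix_tsv format requires a group-label file")
    mat_df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    probe_map <- stats::setNames(normalize_symbols(mat_df[[2]]), mat_df[[1]])
    m <- as.matrix(mat_df[, -(1:2), drop = FALSE])
    rownames(m) <- mat_df[[1]]
    lab <- utils::read.delim(labels, header = FALSE, stringsAsFactors = FALSE)
    grp <- stats::setNames(tolower(lab[[2]]), lab[[1]])
    study <- list(matrix = m, groups = grp, probe_map = probe_map)
  }
  samples <- colnames(study$matrix)
  missing <- setdiff(samples, names(study$groups))
  if (length(missing)) {
    stop(sprintf("sample(s) without a group label: %s",
                 paste(missing, collapse = ", ")))
  }
  grp <- study$groups[samples]
  grp <- ifelse(grepl("control|healthy|normal", grp, ignore.case = TRUE),
                "control", "case")
  grp <- factor(grp, levels = c("control", "case"))
  if (!all(c("control", "case") %in% grp)) stop("both groups must be nonempty")
  m <- study$matrix
  storage.mode(m) <- "double"
  bad <- apply(m, 1, function(r) any(!is.finite(r)))
  if (any(bad)) {
    message(sum(bad), " probe(s) with non-numeric values dropped")
    m <- m[!bad, , drop = FALSE]
  }
  if (scale == "auto") {
    scale <- if (nrow(m) && min(m) < 0 && max(m) <= 30) "log2" else "linear"
  }
  structure(list(matrix = m, groups = stats::setNames(grp, samples),
                 probe_map = study$probe_map[rownames(m)], scale = scale),
            class = "expression_study")
}

parse_soft_gds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # ^SUBSET sections define sample groups ("disease state" subsets)
  groups <- character()
  subset_desc <- NA_character_
  subset_type <- NA_character_
  subset_ids <- NA_character_
  flush_subset <- function(groups) {
    if (!is.na(subset_ids) &&
        (is.na(subset_type) || grepl("disease", subset_type, ignore.case = TRUE))) {
      ids <- trimws(strsplit(subset_ids, ",", fixed = TRUE)[[1]])
      groups[ids] <- subset_desc
    }
    groups
  }
  table_start <- NA_integer_
  table_end <- NA_integer_
  in_subset <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "^SUBSET")) {
      if (in_subset) groups <- flush_subset(groups)
      in_subset <- TRUE
      subset_desc <- subset_type <- subset_ids <- NA_character_
    } else if (startsWith(ln, "!subset_description")) {
      subset_desc <- trimws(sub("^[^=]*=", "", ln))
    } else if (startsWith(ln, "!subset_type")) {
      subset_type <- trimws(sub("^[^=]*=", "", ln))
    } else if (startsWith(ln, "!subset_sample_id")) {
      subset_ids <- trimws(sub("^[^=]*=", "", ln))
    } else if (startsWith(ln, "!dataset_table_begin")) {
      if (in_subset) { groups <- flush_subset(groups); in_subset <- FALSE }
      table_start <- i + 1L
    } else if (startsWith(ln, "!dataset_table_end")) {
      table_end <- i - 1L
    }
  }
  if (in_subset) groups <- flush_subset(groups)
  if (is.na(table_start)) stop("no !dataset_table_begin block found")
  if (is.na(table_end)) table_end <- length(lines)
  if (!length(groups)) stop("no sample group (disease state) subsets found")
  header <- strsplit(lines[table_start], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:2], c("ID_REF", "IDENTIFIER"))) {
    stop("dataset table must start with ID_REF and IDENTIFIER columns")
  }
  body <- lines[(table_start + 1L):table_end]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  probes <- vapply(fields, `[`, "", 1L)
  genes <- vapply(fields, `[`, "", 2L)
  vals <- t(vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[-(1:2)]))
  }, numeric(length(header) - 2L)))
  colnames(vals) <- header[-(1:2)]
  rownames(vals) <- probes
  list(matrix = vals, groups = groups,
       probe_map = stats::setNames(normalize_symbols(genes), probes))
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study: %d probes x %d samples (%d case, %d control), %s scale\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$groups == "case"),
              sum(x$groups == "control"), x$scale))
  invisible(x)
}

# linear-scale matrix regardless of the stored scale
linear_matrix <- function(study) {
  if (study$scale == "log2") 2^study$matrix else study$matrix
}

#' Two-tailed two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] with an explicit variance mode and
#' the degenerate-variance conventions used by the pipeline: when both
#' groups have zero variance, equal means give `p = 1` and unequal means
#' give `p = 0` with a warning.
#'
#' @param case,control numeric vectors, each of length at least 2.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @return list with `t` and `p`.
#' @export
t_test_two_tailed <- function(case, control, variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(length(case) >= 2, length(control) >= 2)
  if (stats::var(case) == 0 && stats::var(control) == 0) {
    if (mean(case) == mean(control)) return(list(t = 0, p = 1))
    warning("zero variance in both groups with unequal means: p -> 0")
    return(list(t = sign(mean(case) - mean(control)) * Inf, p = 0))
  }
  res <- stats::t.test(case, control, var.equal = (variance_mode == "pooled"))
  list(t = unname(res$statistic), p = res$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-down BH adjustment: cumulative minimum, from the largest rank, of
#' `p(i) * m / i`, capped at 1, returned in input order. Delegates to
#' [stats::p.adjust()] after validating the inputs.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-gene differential expression
#'
#' Per-probe linear-scale fold change (mean case / mean control) and
#' two-tailed t-test, aggregated probe-to-gene, with BH FDR across genes.
#' Multi-probe genes are bridged by the chosen aggregation rule; the default
#' keeps the probe with the smallest nominal p.
#'
#' @param study an `expression_study`.
#' @param genes optional character vector restricting the genes tested.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @param aggregate probe-to-gene rule: `"min_p"` (default), `"mean"`
#'   (average the probes before testing), or `"max_abs_logfc"`.
#' @return a `data.frame` with columns `gene`, `probe`, `fold_change`,
#'   `t_statistic`, `p_nominal`, `p_fdr`, `direction`, sorted by `p_nominal`.
#' @export
differential_expression <- function(study, genes = NULL,
                                    variance_mode = c("welch", "pooled"),
                                    aggregate = c("min_p", "mean", "max_abs_logfc")) {
  variance_mode <- match.arg(variance_mode)
  aggregate <- match.arg(aggregate)
  m <- linear_matrix(study)
  case_idx <- study$groups == "case"
  map <- study$probe_map
  if (!is.null(genes)) {
    genes <- normalize_symbols(genes)
    keep <- names(map)[map %in% genes]
    m <- m[intersect(rownames(m), keep), , drop = FALSE]
    map <- map[rownames(m)]
  }
  if (!nrow(m)) stop("no probes left to test")
  probe_stat <- function(vals) {
    mc <- mean(vals[case_idx]); mk <- mean(vals[!case_idx])
    if (mc <= 0 || mk <= 0) {
      stop("nonpositive group mean: input looks centered or unnormalized")
    }
    tt <- t_test_two_tailed(vals[case_idx], vals[!case_idx], variance_mode)
    c(fc = mc / mk, t = tt$t, p = tt$p)
  }
  rows <- lapply(unique(map), function(g) {
    probes <- names(map)[map == g]
    if (aggregate == "mean" && length(probes) > 1) {
      vals <- colMeans(m[probes, , drop = FALSE])
      st <- probe_stat(vals)
      return(data.frame(gene = g, probe = paste(probes, collapse = ";"),
                        fold_change = st[["fc"]], t_statistic = st[["t"]],
                        p_nominal = st[["p"]], stringsAsFactors = FALSE))
    }
    st <- vapply(probes, function(pr) probe_stat(m[pr, ]), numeric(3))
    pick <- if (aggregate == "max_abs_logfc") {
      which.max(abs(log(st["fc", ])))
    } else {
      which.min(st["p", ])
    }
    data.frame(gene = g, probe = probes[pick], fold_change = st["fc", pick],
               t_statistic = st["t", pick], p_nominal = st["p", pick],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_fdr(res$p_nominal)
  res$direction <- ifelse(res$fold_change > 1, "up",
                          ifelse(res$fold_change < 1, "down", "flat"))
  res <- res[order(res$p_nominal, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fold change for one gene
#'
#' Linear-scale ratio of group means (case over control), aggregated
#' probe-to-gene with the same conventions as [differential_expression()].
#'
#' @inheritParams differential_expression
#' @param gene a single gene symbol.
#' @return the fold change (a single positive number).
#' @export
fold_change <- function(study, gene, variance_mode = "welch", aggregate = "min_p") {
  res <- differential_expression(study, genes = gene,
                                 variance_mode = variance_mode,
                                 aggregate = aggregate)
  if (!nrow(res)) stop(sprintf("gene '%s' has no probes in the study", gene))
  res$fold_change[1]
}

#' Volcano-style significance classification
#'
#' Labels genes `upregulated` / `downregulated` / `non-significant` by
#' nominal p-value and fold-change direction, and appends volcano plot
#' coordinates (`log2_fc`, `neg_log10_p`). A gene at fold change exactly 1
#' has no direction and is never called significant.
#'
#' @param results data.frame from [differential_expression()].
#' @param p_threshold nominal significance threshold (default 0.05).
#' @param fc_threshold fold-change reference point (default 1); genes above
#'   it go up, below it go down.
#' @return `results` with `label`, `log2_fc`, `neg_log10_p` columns added.
#' @export
classify_de <- function(results, p_threshold = 0.05, fc_threshold = 1) {
  stopifnot(p_threshold > 0, fc_threshold > 0)
  label <- rep("non-significant", nrow(results))
  sig <- results$p_nominal < p_threshold
  label[sig & results$fold_change > fc_threshold] <- "upregulated"
  label[sig & results$fold_change < fc_threshold] <- "downregulated"
  results$label <- label
  results$log2_fc <- log2(results$fold_change)
  results$neg_log10_p <- -log10(results$p_nominal)
  results
}
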