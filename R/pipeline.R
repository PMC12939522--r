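#' Pipeline configuration
#'
#' Collects input paths, thresholds and proximity settings for
#' [run_pipeline()]. Defaults equal the analysis' standard settings:
#' relevance cutoff 20, interaction confidence 0.7, top 5 percent per
#' centrality metric, all five metrics for the consensus, top 10 percent of
#' the core for the refined set, 10,000 permutations, p < 0.05 and
#' FDR < 0.05.
#'
#' @param symptom_tables character vector of symptom relevance-table paths.
#' @param ppi path to a confidence-scored edge list.
#' @param expression optional path to a SOFT GDS expression file (the
#'   expression stage runs only when supplied).
#' @param gmt optional path to a GMT pathway file (the enrichment stage runs
#'   only when supplied).
#' @param disease_core optional path to a one-symbol-per-line comparator
#'   gene list.
#' @param relevance_threshold relevance cutoff (inclusive, default 20).
#' @param confidence_threshold interaction-confidence cutoff (default 0.7).
#' @param top_fraction top fraction per centrality metric (default 0.05).
#' @param refined_decile top fraction of the core for the refined set
#'   (default 0.10).
#' @param p_threshold nominal significance threshold (default 0.05).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param target drug-target gene for the proximity stage (default "TNF";
#'   `NULL` disables the stage).
#' @param n_permutations permutation count (default 10000).
#' @param seed master seed; stage-local seeds derive from it.
#' @param network_mode symptom-network construction, `"bipartite"` or
#'   `"projection"`.
#' @param out_dir optional output directory; when set, per-stage TSV/JSON
#'   outputs are written there.
#' @return an object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(symptom_tables, ppi,
                            expression = NULL, gmt = NULL, disease_core = NULL,
                            relevance_threshold = 20,
                            confidence_threshold = 0.7,
                            top_fraction = 0.05,
                            refined_decile = 0.10,
                            p_threshold = 0.05,
                            fdr_threshold = 0.05,
                            target = "TNF",
                            n_permutations = 10000,
                            seed = 1L,
                            network_mode = c("bipartite", "projection"),
                            out_dir = NULL) {
  network_mode <- match.arg(network_mode)
  cfg <- list(symptom_tables = as.character(symptom_tables),
              ppi = ppi, expression = expression, gmt = gmt,
              disease_core = disease_core,
              relevance_threshold = relevance_threshold,
              confidence_threshold = confidence_threshold,
              top_fraction = top_fraction,
              refined_decile = refined_decile,
              p_threshold = p_threshold, fdr_threshold = fdr_threshold,
              target = target, n_permutations = n_permutations,
              seed = as.integer(seed), network_mode = network_mode,
              out_dir = out_dir)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  num_in <- function(x, lo, hi, strict_lo = FALSE) {
    is.numeric(x) && length(x) == 1 && is.finite(x) &&
      (if (strict_lo) x > lo else x >= lo) && x <= hi
  }
  if (!length(cfg$symptom_tables)) stop("config error: no symptom tables given")
  for (p in c(cfg$symptom_tables, cfg$ppi, cfg$expression, cfg$gmt,
              cfg$disease_core)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("config error: input path does not exist: %s", p))
    }
  }
  if (!num_in(cfg$relevance_threshold, 0, Inf)) {
    stop("config error: relevance_threshold must be nonnegative")
  }
  if (!num_in(cfg$confidence_threshold, 0, 1)) {
    stop("config error: confidence_threshold must lie in [0, 1]")
  }
  if (!num_in(cfg$top_fraction, 0, 1, strict_lo = TRUE)) {
    stop("config error: top_fraction must lie in (0, 1]")
  }
  if (!num_in(cfg$refined_decile, 0, 1, strict_lo = TRUE)) {
    stop("config error: refined_decile must lie in (0, 1]")
  }
  if (!num_in(cfg$p_threshold, 0, 1, strict_lo = TRUE) ||
      !num_in(cfg$fdr_threshold, 0, 1, strict_lo = TRUE)) {
    stop("config error: significance thresholds must lie in (0, 1]")
  }
  if (!num_in(cfg$n_permutations, 1, Inf)) {
    stop("config error: n_permutations must be at least 1")
  }
  invisible(cfg)
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round trip: `read_pipeline_config(write_pipeline_config(cfg, path))`
#' reproduces the configuration exactly.
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return the path (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$seed <- as.integer(raw$seed)
  do.call(pipeline_config, raw)
}

#' Run the symptom-centered network pharmacology pipeline
#'
#' Executes the stages in order: symptom-set construction (relevance filter,
#' union merge), centrality scoring on the symptom network, per-metric
#' top-fraction selection and consensus core, PPI refinement, optional
#' expression validation, drug-target proximity with permutation null,
#' refined-set construction (target neighbors plus top-decile central core
#' genes), and optional pathway over-representation. When `out_dir` is set,
#' per-stage tables and a JSON summary are written there.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_result`: a list of per-stage results
#'   plus a `summary` of the stage counts (union, at-least-2, all-metric
#'   consensus, refined core, neighbors, refined set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  res <- list(config = config)

  # symptom gene sets
  table <- read_symptom_tables(config$symptom_tables)
  sets <- filter_by_relevance(table, config$relevance_threshold)
  union_set <- union_merge(sets)
  venn <- membership_counts(sets)
  res$sets <- list(table = table, sets = sets, union = union_set, venn = venn)

  # centrality consensus on the symptom network
  net <- build_symptom_network(sets, mode = config$network_mode)
  ctab <- symptom_centrality(net)
  scores <- lapply(centrality_metrics(), function(m) {
    stats::setNames(ctab[[m]], ctab$gene)
  })
  names(scores) <- centrality_metrics()
  per_metric_top <- lapply(scores, top_fraction, fraction = config$top_fraction)
  top_venn <- membership_counts(per_metric_top)
  candidate <- consensus_core(per_metric_top,
                              min_metrics = length(per_metric_top))
  res$centrality <- list(network = net, table = ctab,
                         per_metric_top = per_metric_top, venn = top_venn,
                         candidate = candidate)

  # PPI refinement
  ppi <- read_edge_list(config$ppi, min_confidence = config$confidence_threshold)
  core <- ppi_refine(candidate, ppi)
  res$ppi <- ppi
  res$core <- core

  # optional expression validation of the refined core
  if (!is.null(config$expression)) {
    study <- load_expression(config$expression, format = "soft")
    tested <- intersect(core$refined, unique(study$probe_map))
    if (length(tested)) {
      de <- differential_expression(study, genes = tested)
      de <- classify_de(de, p_threshold = config$p_threshold)
      res$expression <- list(study = study, de = de)
    }
  }

  # drug-target proximity
  if (!is.null(config$target) &&
      normalize_symbols(config$target) %in% igraph::V(ppi)$name) {
    prox <- proximity_test(ppi, config$target, core$refined,
                           n_permutations = config$n_permutations,
                           seed = derive_seed(config$seed, 5L))
    res$proximity <- prox
    # refined set: target neighbors + top-decile central core genes
    deg_sc <- stats::setNames(ctab$degree, ctab$gene)
    res$refined_set <- refined_gene_set(prox$direct_neighbors, deg_sc,
                                        core$refined,
                                        decile = config$refined_decile)
  }

  # optional over-representation analysis
  if (!is.null(config$gmt) && !is.null(res$refined_set)) {
    pc <- read_gmt(config$gmt)
    res$enrichment <- ora_hypergeometric(res$refined_set, pc)
  }

  # optional disease-core comparison
  if (!is.null(config$disease_core)) {
    dc <- normalize_symbols(readLines(config$disease_core, warn = FALSE))
    dc <- dc[nzchar(dc)]
    res$disease_core <- list(genes = dc,
                             overlap = intersect_sets(dc, core$refined))
  }

  res$summary <- list(
    n_union = length(union_set),
    n_at_least_2 = unname(top_venn$at_least[2]),
    n_consensus = length(candidate),
    n_refined_core = length(core$refined),
    n_neighbors = if (!is.null(res$proximity))
      length(res$proximity$direct_neighbors) else NA_integer_,
    n_refined_set = if (!is.null(res$refined_set))
      length(res$refined_set) else NA_integer_,
    seed = config$seed
  )
  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(res$sets$union, file.path(out_dir, "union_genes.txt"))
  wtsv(res$centrality$table, "centrality_table.tsv")
  mm <- membership_matrix(res$centrality$per_metric_top)
  wtsv(data.frame(gene = rownames(mm), mm + 0, check.names = FALSE),
       "consensus_membership.tsv")
  writeLines(res$core$refined, file.path(out_dir, "refined_core.txt"))
  wtsv(res$core$removed, "removal_log.tsv")
  if (!is.null(res$expression)) wtsv(res$expression$de, "de_table.tsv")
  if (!is.null(res$proximity)) {
    p <- res$proximity
    jsonlite::write_json(
      list(target = p$target, observed_mean_distance = p$observed_mean_distance,
           null_mean = p$null_mean, null_sd = p$null_sd, z = p$z, p = p$p,
           n_permutations = p$n_permutations, seed = p$seed,
           direct_neighbors = p$direct_neighbors, unreachable = p$unreachable),
      file.path(out_dir, "proximity.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$refined_set)) {
    writeLines(res$refined_set, file.path(out_dir, "refined_set.txt"))
  }
  if (!is.null(res$enrichment)) wtsv(res$enrichment, "enrichment.tsv")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Symptom-centered network pharmacology pipeline\n")
  cat(sprintf("  union of symptom gene sets:  %4d genes\n", s$n_union))
  cat(sprintf("  top-%g%% in >=2 metrics:      %4d genes\n",
              100 * x$config$top_fraction, s$n_at_least_2))
  cat(sprintf("  all-metric consensus:        %4d genes\n", s$n_consensus))
  cat(sprintf("  PPI-refined core:            %4d genes\n", s$n_refined_core))
  if (!is.na(s$n_neighbors)) {
    cat(sprintf("  %s direct neighbors:    %4d (refined set: %d genes)\n",
                x$proximity$target, s$n_neighbors, s$n_refined_set))
  }
  invisible(x)
}

#' Packaged gene-list fixtures
#'
#' Returns the gene lists shipped with the package: `"table1"`, the five
#' top-5-percent centrality gene lists of the symptom network (a named list
#' of five character vectors, with scores available via
#' `fixtures("table1_scores")`); `"disease_core18"`, the 18-gene
#' disease-centric comparator core; `"tnf13"`, the 13 core genes directly
#' connected to TNF; `"central14"`, the 14 top-decile central core genes.
#'
#' @param name one of `"table1"`, `"table1_scores"`, `"disease_core18"`,
#'   `"tnf13"`, `"central14"`.
#' @return a character vector, or a named list for the table fixtures.
#' @export
fixtures <- function(name = c("table1", "table1_scores", "disease_core18",
                              "tnf13", "central14")) {
  name <- match.arg(name)
  path <- function(f) system.file("extdata", f, package = "sympnet",
                                  mustWork = TRUE)
  if (name %in% c("table1", "table1_scores")) {
    df <- utils::read.delim(path("table1_top5_centrality.tsv"),
                            stringsAsFactors = FALSE)
    out <- lapply(centrality_metrics(), function(m) {
      g <- df[[paste0(m, "_gene")]]
      s <- df[[paste0(m, "_score")]]
      keep <- !is.na(g) & nzchar(g)
      if (name == "table1") normalize_symbols(g[keep])
      else stats::setNames(as.numeric(s[keep]), normalize_symbols(g[keep]))
    })
    names(out) <- centrality_metrics()
    return(out)
  }
  f <- switch(name,
              disease_core18 = "disease_core18.txt",
              tnf13 = "tnf_neighbors13.txt",
              central14 = "central_top14.txt")
  normalize_symbols(readLines(path(f), warn = FALSE))
}
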