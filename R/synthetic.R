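#' Specification for the synthetic-data generators
#'
#' Bundles the parameters of all four generators behind a single seeded
#' specification, so a whole synthetic study (symptom relevance tables, PPI
#' edge list, case-control expression, pathway annotation) is reproducible
#' from one object. Defaults emulate the structure of the emulated
#' resources: 24 symptom terms (matching the 1/24 quantization seen in
#' two-mode gene-symptom degree scores), gamma-shaped relevance scores whose
#' mass straddles the 20 cutoff, a preferential-attachment interaction
#' network with edge confidences spanning the 0.7 filter, a 16 vs 16
#' case-control blood-microarray-sized expression study with multiplicative
#' log-normal noise, and one planted enriched pathway.
#'
#' @param seed integer master seed; every generator derives its own stream
#'   from it deterministically.
#' @param n_genes number of background gene symbols.
#' @param n_symptoms number of symptom terms (default 24).
#' @param n_hubs number of planted hub genes.
#' @param hub_symptom_prob probability a hub attaches to each symptom.
#' @param background_symptom_prob probability a background gene attaches to
#'   each symptom.
#' @param hub_relevance,background_relevance `c(shape, scale)` of the gamma
#'   relevance-score distributions for hub and background attachments.
#' @param ppi_model `"preferential"` (Barabasi-Albert) or `"random"`
#'   (Erdos-Renyi).
#' @param ppi_m edges added per vertex in the preferential-attachment model
#'   (or expected density control for `"random"`).
#' @param confidence_range range the edge confidences are drawn from.
#' @param target_gene optional drug-target analogue wired into the PPI.
#' @param target_wiring `"hubs"` (wired to the planted hubs: proximal) or
#'   `"uniform"` (wired to random genes: null-like).
#' @param target_degree number of edges given to the target gene.
#' @param n_case,n_control expression sample sizes per group.
#' @param planted_fc named vector of planted linear fold changes
#'   (case/control); unnamed genes are generated at fold change 1.
#' @param n_null_genes number of additional fold-change-1 genes in the
#'   expression study.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param n_pathways number of random pathways in the GMT output.
#' @param pathway_size nominal pathway size.
#' @param planted_overlap fraction of the planted pathway drawn from the
#'   designated query set.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 400L,
                           n_symptoms = 24L,
                           n_hubs = 8L,
                           hub_symptom_prob = 0.9,
                           background_symptom_prob = 0.15,
                           hub_relevance = c(shape = 10, scale = 4),
                           background_relevance = c(shape = 2, scale = 6),
                           ppi_model = c("preferential", "random"),
                           ppi_m = 3L,
                           confidence_range = c(0.4, 1.0),
                           target_gene = "TARGET1",
                           target_wiring = c("hubs", "uniform"),
                           target_degree = 13L,
                           n_case = 16L,
                           n_control = 16L,
                           planted_fc = c(DEG1 = 2.0, DEG2 = 1.5, DEG3 = 1.35),
                           n_null_genes = 60L,
                           noise_cv = 0.1,
                           n_pathways = 50L,
                           pathway_size = 30L,
                           planted_overlap = 0.8) {
  ppi_model <- match.arg(ppi_model)
  target_wiring <- match.arg(target_wiring)
  stopifnot(n_genes >= 10, n_symptoms >= 1, n_hubs >= 1, n_hubs < n_genes,
            hub_symptom_prob >= 0, hub_symptom_prob <= 1,
            background_symptom_prob >= 0, background_symptom_prob <= 1,
            ppi_m >= 1, noise_cv > 0, n_case >= 2, n_control >= 2,
            all(planted_fc > 0), planted_overlap > 0, planted_overlap <= 1,
            n_pathways >= 1, pathway_size >= 2)
  genes <- sprintf("G%04d", seq_len(n_genes))
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_symptoms = as.integer(n_symptoms),
    genes = genes, hub_genes = hubs,
    hub_symptom_prob = hub_symptom_prob,
    background_symptom_prob = background_symptom_prob,
    hub_relevance = hub_relevance, background_relevance = background_relevance,
    ppi_model = ppi_model, ppi_m = as.integer(ppi_m),
    confidence_range = confidence_range,
    target_gene = normalize_symbols(target_gene),
    target_wiring = target_wiring, target_degree = as.integer(target_degree),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    planted_fc = planted_fc, n_null_genes = as.integer(n_null_genes),
    noise_cv = noise_cv,
    n_pathways = as.integer(n_pathways), pathway_size = as.integer(pathway_size),
    planted_overlap = planted_overlap
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study spec (seed %d): %d genes + %d hubs, ",
                     "%d symptoms; %s PPI (m=%d); %d+%d expression samples; ",
                     "%d pathways\n"),
              x$seed, x$n_genes, length(x$hub_genes), x$n_symptoms,
              x$ppi_model, x$ppi_m, x$n_case, x$n_control, x$n_pathways))
  invisible(x)
}

#' Generate per-symptom relevance tables
#'
#' Writes one two-column tab-separated table (`gene  relevance_score`) per
#' symptom term. Hub genes attach to most symptoms with relevance scores
#' mostly above the 20 cutoff; background genes attach sparsely with scores
#' mostly below it.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `paths` and the combined long-format
#'   `table`.
#' @export
gen_symptom_tables <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  symptoms <- sprintf("symptom%02d", seq_len(spec$n_symptoms))
  all_rows <- with_seed(derive_seed(spec$seed, 1L), {
    rows <- list()
    for (s in symptoms) {
      hub_on <- stats::runif(length(spec$hub_genes)) < spec$hub_symptom_prob
      bg_on <- stats::runif(length(spec$genes)) < spec$background_symptom_prob
      g <- c(spec$hub_genes[hub_on], spec$genes[bg_on])
      rel <- c(
        stats::rgamma(sum(hub_on), shape = spec$hub_relevance[["shape"]],
                      scale = spec$hub_relevance[["scale"]]),
        stats::rgamma(sum(bg_on), shape = spec$background_relevance[["shape"]],
                      scale = spec$background_relevance[["scale"]])
      )
      rows[[s]] <- data.frame(gene = g, symptom = s,
                              relevance = round(rel, 3),
                              stringsAsFactors = FALSE)
    }
    rows
  })
  paths <- character(length(symptoms))
  names(paths) <- symptoms
  for (s in symptoms) {
    p <- file.path(dir, paste0(s, ".tsv"))
    df <- all_rows[[s]]
    utils::write.table(df[c("gene", "relevance")], p, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths[s] <- p
  }
  invisible(list(paths = paths, table = do.call(rbind, all_rows)))
}

#' Generate a confidence-scored PPI edge list
#'
#' Grows a connected preferential-attachment (or random) interaction graph
#' over the background genes, renames the highest-degree vertices to the
#' planted hub genes so topological and symptom-level hubness coincide,
#' draws per-edge confidences uniformly over `confidence_range` (so a 0.7
#' filter removes a controllable fraction), and optionally wires in a
#' drug-target analogue connected either to the hubs or uniformly at random.
#'
#' @param spec a [synthetic_spec()].
#' @param path output path for the tab-separated edge list.
#' @return invisibly, the generated `igraph` network.
#' @export
gen_ppi <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  net <- with_seed(derive_seed(spec$seed, 2L), {
    n <- spec$n_genes
    g <- if (spec$ppi_model == "preferential") {
      igraph::sample_pa(n, power = 1, m = spec$ppi_m, directed = FALSE)
    } else {
      igraph::sample_gnm(n, m = spec$ppi_m * (n - 1), directed = FALSE)
    }
    # highest-degree vertices become the planted hubs
    deg_order <- order(igraph::degree(g), decreasing = TRUE)
    vnames <- character(n)
    vnames[deg_order[seq_along(spec$hub_genes)]] <- spec$hub_genes
    rest <- setdiff(spec$genes, character(0))
    vnames[vnames == ""] <- rest[seq_len(sum(vnames == ""))]
    igraph::V(g)$name <- vnames
    igraph::E(g)$confidence <- stats::runif(igraph::ecount(g),
                                            spec$confidence_range[1],
                                            spec$confidence_range[2])
    if (!is.null(spec$target_gene) && nzchar(spec$target_gene)) {
      anchors <- if (spec$target_wiring == "hubs") {
        pool <- c(spec$hub_genes,
                  sample(setdiff(vnames, spec$hub_genes),
                         max(0, spec$target_degree - length(spec$hub_genes))))
        pool[seq_len(min(spec$target_degree, length(pool)))]
      } else {
        sample(vnames, spec$target_degree)
      }
      g <- igraph::add_vertices(g, 1, name = spec$target_gene)
      g <- igraph::add_edges(g, rbind(spec$target_gene, anchors),
                             confidence = stats::runif(length(anchors), 0.75, 1))
    }
    g
  })
  write_edge_list(net, path)
  invisible(net)
}

#' Generate a case-control expression study in the SOFT GDS dialect
#'
#' Per gene: a log-normal baseline intensity, control samples at baseline
#' with multiplicative log-normal noise of coefficient of variation
#' `noise_cv`, case samples additionally multiplied by the planted fold
#' change. Genes get one or two probes. Group labels are written as
#' "disease state" subset sections. The study covers the planted
#' fold-change genes, the spec's hub genes (fold change 1 unless planted),
#' and `n_null_genes` additional null genes.
#'
#' @param spec a [synthetic_spec()].
#' @param path output path for the SOFT file.
#' @return invisibly, the `expression_study` as loaded back from `path`.
#' @export
gen_expression <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, 3L), {
    null_genes <- sprintf("NULL%03d", seq_len(spec$n_null_genes))
    hub_flat <- setdiff(spec$hub_genes, names(spec$planted_fc))
    fc <- c(spec$planted_fc,
            stats::setNames(rep(1, length(hub_flat)), hub_flat),
            stats::setNames(rep(1, spec$n_null_genes), null_genes))
    genes <- names(fc)
    n_probe <- sample(1:2, length(genes), replace = TRUE)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    samples <- c(sprintf("GSM_CASE%02d", seq_len(spec$n_case)),
                 sprintf("GSM_CTRL%02d", seq_len(spec$n_control)))
    grp <- rep(c("case", "control"), c(spec$n_case, spec$n_control))
    rows <- list()
    for (i in seq_along(genes)) {
      base <- stats::rlnorm(1, meanlog = log(500), sdlog = 0.5)
      for (pr in seq_len(n_probe[i])) {
        mu <- base * ifelse(grp == "case", fc[i], 1)
        vals <- mu * stats::rlnorm(length(samples), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog)
        rows[[length(rows) + 1L]] <- c(sprintf("P_%s_%d", genes[i], pr),
                                       genes[i],
                                       formatC(vals, format = "f", digits = 4))
      }
    }
    header <- c("ID_REF", "IDENTIFIER", samples)
    out <- c(
      "^DATASET = synthetic_gds",
      "!dataset_title = Synthetic ankylosing spondylitis: blood",
      "^SUBSET = case",
      "!subset_type = disease state",
      "!subset_description = ankylosing spondylitis",
      paste0("!subset_sample_id = ",
             paste(samples[grp == "case"], collapse = ",")),
      "^SUBSET = control",
      "!subset_type = disease state",
      "!subset_description = control",
      paste0("!subset_sample_id = ",
             paste(samples[grp == "control"], collapse = ",")),
      "!dataset_table_begin",
      paste(header, collapse = "\t"),
      vapply(rows, paste, character(1), collapse = "\t"),
      "!dataset_table_end"
    )
    writeLines(out, path)
  })
  invisible(load_expression(path, format = "soft"))
}

#' Generate a GMT pathway file with one planted enriched set
#'
#' Random pathways are drawn from the spec's gene pool; the planted pathway
#' draws `planted_overlap` of its members from the designated query set and
#' fills the rest at random, so over-representation analysis of the query
#' should rank it first at the default effect size.
#'
#' @param spec a [synthetic_spec()].
#' @param path output path for the GMT file.
#' @param query character vector the planted pathway is enriched for
#'   (default: the spec's hub genes plus target gene).
#' @return invisibly, the `pathway_collection` as read back from `path`.
#' @export
gen_pathways <- function(spec, path, query = c(spec$hub_genes, spec$target_gene)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  query <- unique(normalize_symbols(query))
  with_seed(derive_seed(spec$seed, 4L), {
    pool <- unique(c(spec$genes, spec$hub_genes, query))
    lines <- character(spec$n_pathways + 1L)
    for (i in seq_len(spec$n_pathways)) {
      members <- sample(pool, spec$pathway_size)
      lines[i] <- paste(c(sprintf("RANDOM_PATHWAY_%02d", i), "random background set",
                          members), collapse = "\t")
    }
    k_planted <- max(1L, round(spec$planted_overlap *
                                 min(spec$pathway_size, length(query))))
    planted <- c(sample(query, k_planted),
                 sample(setdiff(pool, query), spec$pathway_size - k_planted))
    lines[spec$n_pathways + 1L] <- paste(c("PLANTED_PATHWAY",
                                           "planted enriched set", planted),
                                         collapse = "\t")
    writeLines(lines, path)
  })
  invisible(read_gmt(path))
}
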