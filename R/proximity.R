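#' BFS hop distances from a source gene to a target set
#'
#' Unweighted shortest-path distances from `source` to each member of
#' `targets`. Unreachable targets (including targets absent from the
#' network) are recorded separately and excluded from any mean. The source
#' itself, if listed among the targets, is excluded by default.
#'
#' @param net an `igraph` network.
#' @param source gene symbol present in `net`.
#' @param targets character vector of target genes.
#' @param include_source include the source (distance 0) if it appears in
#'   `targets`?
#' @return list with `distances` (named numeric, finite) and `unreachable`
#'   (character).
#' @export
shortest_distances <- function(net, source, targets, include_source = FALSE) {
  source <- normalize_symbols(source)
  targets <- unique(normalize_symbols(targets))
  if (!source %in% igraph::V(net)$name) {
    stop(sprintf("source gene '%s' is not in the network", source))
  }
  if (!include_source) targets <- setdiff(targets, source)
  in_net <- targets[targets %in% igraph::V(net)$name]
  d_all <- igraph::distances(net, v = source, weights = NA)[1, ]
  d <- d_all[in_net]
  finite <- is.finite(d)
  list(distances = d[finite],
       unreachable = sort(c(setdiff(targets, in_net), in_net[!finite])))
}

#' Observed network proximity
#'
#' Arithmetic mean of the finite shortest-path distances; the network
#' proximity score of a target relative to a gene set.
#'
#' @param distances named numeric vector of finite distances, or the list
#'   returned by [shortest_distances()].
#' @return mean distance (a single number).
#' @export
observed_proximity <- function(distances) {
  if (is.list(distances)) distances <- distances$distances
  distances <- distances[is.finite(distances)]
  if (!length(distances)) stop("all targets unreachable: proximity undefined")
  mean(distances)
}

#' Permutation null for network proximity
#'
#' Draws `n_permutations` gene sets of size `set_size` uniformly without
#' replacement from the network's nodes excluding the source, computes each
#' set's mean distance from the source exactly as for the observed set, and
#' summarizes the null by its sample mean and population-convention standard
#' deviation (divide by n). A fixed seed reproduces the samples exactly.
#'
#' @param net an `igraph` network.
#' @param source source gene symbol.
#' @param set_size size of each sampled gene set.
#' @param n_permutations number of sampled sets (default 10000).
#' @param seed integer RNG seed.
#' @param include_source passed through to the distance convention.
#' @return list with `mu`, `sigma`, `samples`, `n_permutations`, `seed`.
#' @export
permutation_null <- function(net, source, set_size, n_permutations = 10000,
                             seed = 1L, include_source = FALSE) {
  source <- normalize_symbols(source)
  if (!source %in% igraph::V(net)$name) {
    stop(sprintf("source gene '%s' is not in the network", source))
  }
  pool <- setdiff(igraph::V(net)$name, source)
  stopifnot(set_size >= 1, n_permutations >= 1)
  if (length(pool) < set_size) {
    stop("network has fewer nodes (excluding the source) than set_size")
  }
  d_all <- igraph::distances(net, v = source, weights = NA)[1, ]
  d_pool <- d_all[pool]
  samples <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      d <- d_pool[sample.int(length(d_pool), set_size)]
      d <- d[is.finite(d)]
      if (!length(d)) NA_real_ else mean(d)
    }, numeric(1))
  })
  samples <- samples[!is.na(samples)]
  mu <- mean(samples)
  sigma <- sqrt(mean((samples - mu)^2))
  if (sigma == 0) {
    stop("degenerate permutation null: zero standard deviation (z undefined)")
  }
  list(mu = mu, sigma = sigma, samples = samples,
       n_permutations = n_permutations, seed = as.integer(seed))
}

#' Proximity z-score and normal-CDF p-value
#'
#' Standardizes the observed mean distance against the permutation null and
#' converts to a one-sided lower-tail p-value from the standard normal CDF:
#' smaller distance means greater proximity, hence smaller p.
#'
#' @param d_obs observed mean distance.
#' @param mu,sigma null mean and standard deviation (`sigma > 0`).
#' @return list with `z` and `p`.
#' @export
proximity_z_p <- function(d_obs, mu, sigma) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  z <- (d_obs - mu) / sigma
  list(z = z, p = stats::pnorm(z))
}

#' Direct neighbors of a target within a gene set
#'
#' Members of `core` adjacent to `target` in the network. The target itself
#' is included when it is listed in `core` and `include_self` is on (the
#' default), so a drug target that is itself a core gene counts as its own
#' first-order neighborhood member.
#'
#' @param net an `igraph` network.
#' @param target gene symbol present in `net`.
#' @param core character vector of gene symbols.
#' @param include_self include the target when it belongs to `core`?
#' @return sorted character vector.
#' @export
direct_neighbors <- function(net, target, core, include_self = TRUE) {
  target <- normalize_symbols(target)
  core <- unique(normalize_symbols(core))
  if (!target %in% igraph::V(net)$name) {
    stop(sprintf("target gene '%s' is not in the network", target))
  }
  nb <- igraph::neighbors(net, target)$name
  res <- intersect(core, nb)
  if (include_self && target %in% core) res <- union(res, target)
  sort(res)
}

#' Drug-target network proximity test
#'
#' End-to-end proximity analysis of one target against a gene set: observed
#' mean shortest-path distance, size-matched uniform permutation null,
#' z-score, lower-tail normal p-value, and the direct-neighbor list.
#'
#' @param net an `igraph` network (typically the full background PPI, so
#'   distances may traverse non-core genes).
#' @param target target gene symbol.
#' @param core character vector, the evaluated gene set.
#' @param n_permutations permutation count (default 10000).
#' @param seed integer RNG seed.
#' @param include_source include the target itself (distance 0) in the
#'   observed mean when it belongs to `core`?
#' @return object of class `proximity_result`.
#' @export
proximity_test <- function(net, target, core, n_permutations = 10000,
                           seed = 1L, include_source = FALSE) {
  sd_res <- shortest_distances(net, target, core, include_source = include_source)
  d_obs <- observed_proximity(sd_res)
  null <- permutation_null(net, target, set_size = length(sd_res$distances),
                           n_permutations = n_permutations, seed = seed,
                           include_source = include_source)
  zp <- proximity_z_p(d_obs, null$mu, null$sigma)
  structure(list(
    target = normalize_symbols(target),
    observed_mean_distance = d_obs,
    null_mean = null$mu,
    null_sd = null$sigma,
    z = zp$z,
    p = zp$p,
    n_permutations = n_permutations,
    seed = as.integer(seed),
    direct_neighbors = direct_neighbors(net, target, core),
    unreachable = sd_res$unreachable,
    n_core = length(unique(normalize_symbols(core)))
  ), class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, digits = 4, ...) {
  cat(sprintf("Network proximity of %s to a %d-gene set\n", x$target, x$n_core))
  cat(sprintf("  observed mean distance: %.*f\n", digits, x$observed_mean_distance))
  cat(sprintf("  null mean (sd):         %.*f (%.*f)  [%d permutations, seed %d]\n",
              digits, x$null_mean, digits, x$null_sd, x$n_permutations, x$seed))
  cat(sprintf("  z = %.*f, p = %.*f (lower tail)\n", digits, x$z, digits, x$p))
  pct <- round(100 * length(x$direct_neighbors) / x$n_core, 1)
  cat(sprintf("  direct neighbors: %d of %d core genes (%.1f%%)\n",
              length(x$direct_neighbors), x$n_core, pct))
  if (length(x$unreachable)) {
    cat(sprintf("  unreachable core genes: %d\n", length(x$unreachable)))
  }
  invisible(x)
}
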