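# Co-occurrence networks of core features: pairwise Spearman correlation
# on absolute abundance, an edge when |rho| > 0.8 with FDR-adjusted
# p < 0.05, Louvain-type modularity modules ("ecological clusters"),
# within/among-module connectivity (Zi/Pi) keystone roles, and robustness
# to random node removal.

#' Pairwise Spearman correlations with p-values
#'
#' Tie-aware Spearman's rho (Pearson on average ranks) for every feature
#' pair, with two-sided p-values from the t approximation on `n - 2`
#' degrees of freedom. Constant features yield `NA` (no possible edge).
#'
#' @param abundance Abundance tibble (samples x features).
#' @param features Optional subset of features (e.g. the core set).
#' @return List with matrices `rho` and `p`, and `n` (sample count).
#' @export
spearman_edges <- function(abundance, features = NULL) {
  m <- as_sample_matrix(abundance)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(m))
    if (length(missing) > 0) {
      cli::cli_abort("Feature{?s} {.val {utils::head(missing, 5)}} not in the table.")
    }
    m <- m[, features, drop = FALSE]
  }
  n <- nrow(m)
  if (n < 4) cli::cli_abort("Need >= 4 samples for correlation testing.")
  constant <- apply(m, 2, function(x) stats::sd(x) == 0)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- NA
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- NA
  list(rho = rho, p = p, n = n)
}

#' Build a thresholded co-occurrence network
#'
#' Adjusts the upper-triangle p-values by Benjamini-Hochberg FDR (family =
#' all testable feature pairs) and keeps an undirected edge between two
#' features when `|rho| > rho_cut` and the adjusted p is below `alpha`.
#' All input features remain nodes of the network, so `average_degree`
#' (2E/N) counts isolated core features — network complexity is compared
#' on a fixed node set.
#'
#' @param cors Result of [spearman_edges()], or a list with `rho` and `p`
#'   matrices.
#' @param rho_cut Absolute correlation threshold (edges need strictly
#'   greater |rho|).
#' @param alpha Significance threshold on the (adjusted) p.
#' @param fdr Adjust p-values by FDR before thresholding?
#' @return A `co_network`: list with `graph` (igraph), `nodes`, `edges`,
#'   `metrics`. Modules are unset until [detect_modules()].
#' @export
build_network <- function(cors, rho_cut = 0.8, alpha = 0.05, fdr = TRUE) {
  rho <- cors$rho
  p <- cors$p
  stopifnot(identical(dim(rho), dim(p)))
  ids <- colnames(rho)
  ut <- upper.tri(rho)
  idx <- which(ut & !is.na(p), arr.ind = TRUE)
  q <- if (fdr) bh_fdr(p[cbind(idx[, 1], idx[, 2])]) else p[cbind(idx[, 1], idx[, 2])]
  r <- rho[cbind(idx[, 1], idx[, 2])]
  keep <- abs(r) > rho_cut & q < alpha
  edges <- tibble::tibble(from = ids[idx[keep, 1]], to = ids[idx[keep, 2]],
                          rho = r[keep], q = q[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  nodes <- tibble::tibble(node = ids,
                          degree = as.numeric(igraph::degree(g))[match(ids, igraph::V(g)$name)],
                          module = NA_character_)
  net <- structure(list(graph = g, nodes = nodes, edges = edges,
                        params = list(rho_cut = rho_cut, alpha = alpha,
                                      fdr = fdr)),
                   class = "co_network")
  net$metrics <- network_metrics(net)
  net
}

network_metrics <- function(net) {
  n <- nrow(net$nodes)
  e <- nrow(net$edges)
  q <- if (all(is.na(net$nodes$module))) NA_real_ else {
    igraph::modularity(net$graph,
                       as.integer(factor(net$nodes$module[
                         match(igraph::V(net$graph)$name, net$nodes$node)])))
  }
  list(n_nodes = n, n_edges = e,
       average_degree = if (n > 0) 2 * e / n else NA_real_,
       modularity_Q = q)
}

#' @export
print.co_network <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Co-occurrence network: %d nodes, %d edges, average degree %.2f\n",
              m$n_nodes, m$n_edges, m$average_degree))
  if (!is.na(m$modularity_Q)) {
    cat(sprintf("  %d modules, modularity Q = %.3f\n",
                dplyr::n_distinct(x$nodes$module), m$modularity_Q))
  }
  invisible(x)
}

#' @method tidy co_network
#' @export
tidy.co_network <- function(x, ...) x$edges

#' @method glance co_network
#' @export
glance.co_network <- function(x, ...) {
  tibble::as_tibble(x$metrics[c("n_nodes", "n_edges", "average_degree")]) |>
    dplyr::mutate(modularity_Q = x$metrics$modularity_Q,
                  n_modules = if (all(is.na(x$nodes$module))) NA_integer_
                              else dplyr::n_distinct(x$nodes$module))
}

#' Detect ecological clusters (modules)
#'
#' Louvain-type greedy modularity maximization on the unweighted edge
#' set, deterministic under the given seed. Modules are relabeled
#' `module1`, `module2`, ... by descending node count; isolated nodes get
#' singleton modules.
#'
#' @param net A `co_network`.
#' @param resolution Resolution parameter of the modularity objective.
#' @param seed Integer seed.
#' @return The network with `nodes$module` filled in and `modularity_Q`
#'   computed.
#' @export
detect_modules <- function(net, resolution = 1.0, seed = 1) {
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$edges) == 0) {
    cli::cli_abort("Cannot detect modules in a network with no edges.")
  }
  g <- net$graph
  comm <- with_seed_if(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  # relabel by descending module size, ties by smallest member name
  sizes <- sort(table(memb), decreasing = TRUE)
  rank <- stats::setNames(seq_along(sizes), names(sizes))
  lab <- module_label(rank[as.character(memb)])
  net$nodes$module <- lab[match(net$nodes$node, igraph::V(g)$name)]
  net$metrics <- network_metrics(net)
  net
}

#' @rdname detect_modules
#' @export
module_membership <- function(net) {
  tibble::tibble(feature_id = net$nodes$node, module = net$nodes$module)
}

#' Node topological roles (Zi/Pi)
#'
#' Within-module degree z-score
#' `Zi = (k_i,within - mean(k_within in module)) / sd(k_within in module)`
#' (0 when the module's within-degrees have zero variance) and
#' among-module connectivity `Pi = 1 - sum_s (k_is / k_i)^2` over the
#' modules `s` a node touches. Roles: `module_hub` (Zi > zi_threshold),
#' `connector` (Pi > pi_threshold), `network_hub` (both), otherwise
#' `peripheral`. Isolated nodes are peripheral with Zi = Pi = 0.
#'
#' @param net A `co_network` with modules assigned.
#' @param zi_threshold,pi_threshold Role thresholds.
#' @return Tibble (`node`, `module`, `degree`, `Zi`, `Pi`, `role`).
#' @export
node_roles <- function(net, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "co_network"))
  if (all(is.na(net$nodes$module))) {
    cli::cli_abort("Assign modules first with {.fn detect_modules}.")
  }
  nodes <- net$nodes$node
  module <- net$nodes$module
  names(module) <- nodes
  edges <- net$edges
  # per-node counts of edges into each module
  inc <- dplyr::bind_rows(
    tibble::tibble(node = edges$from, other = edges$to),
    tibble::tibble(node = edges$to, other = edges$from))
  inc$other_module <- module[inc$other]
  k_total <- stats::setNames(rep(0, length(nodes)), nodes)
  tab <- table(inc$node)
  k_total[names(tab)] <- as.numeric(tab)
  k_within <- stats::setNames(rep(0, length(nodes)), nodes)
  wtab <- table(inc$node[module[inc$node] == inc$other_module])
  k_within[names(wtab)] <- as.numeric(wtab)

  zi <- stats::setNames(rep(0, length(nodes)), nodes)
  for (m in unique(module)) {
    sel <- nodes[module == m]
    mu <- mean(k_within[sel])
    sdv <- stats::sd(k_within[sel])
    if (length(sel) > 1 && !is.na(sdv) && sdv > 0) {
      zi[sel] <- (k_within[sel] - mu) / sdv
    }
  }
  pi <- vapply(nodes, function(v) {
    k <- k_total[[v]]
    if (k == 0) return(0)
    ks <- table(inc$other_module[inc$node == v])
    1 - sum((as.numeric(ks) / k)^2)
  }, numeric(1))
  zi[k_total == 0] <- 0  # isolated nodes: no within-module connectivity

  tibble::tibble(
    node = nodes, module = module, degree = as.numeric(k_total),
    Zi = as.numeric(zi), Pi = as.numeric(pi),
    role = dplyr::case_when(
      zi > zi_threshold & pi > pi_threshold ~ "network_hub",
      zi > zi_threshold ~ "module_hub",
      pi > pi_threshold ~ "connector",
      TRUE ~ "peripheral"))
}

#' Network robustness under random node removal
#'
#' For each repetition, removes `floor(removal_fraction * N)` nodes
#' uniformly at random and records the fraction of surviving nodes that
#' belong to the largest connected component among survivors. Reports the
#' mean and sd over repetitions.
#'
#' @param net A `co_network` or an igraph graph.
#' @param removal_fraction Fraction of nodes removed, in (0, 1).
#' @param reps Number of random removal sets.
#' @param seed Integer seed.
#' @return Tibble (`mean`, `sd`, `reps`, `removal_fraction`, `n_nodes`)
#'   with the per-rep values in the `"values"` attribute.
#' @export
robustness <- function(net, removal_fraction = 0.5, reps = 100, seed = NULL) {
  g <- if (inherits(net, "co_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 2) cli::cli_abort("Need >= 2 nodes.")
  if (removal_fraction <= 0 || removal_fraction >= 1) {
    cli::cli_abort("{.field removal_fraction} must be in (0, 1).")
  }
  n_remove <- floor(removal_fraction * n)
  vals <- with_seed_if(seed, vapply(seq_len(reps), function(i) {
    doomed <- sample.int(n, n_remove)
    sub <- igraph::delete_vertices(g, doomed)
    max(igraph::components(sub)$csize) / igraph::vcount(sub)
  }, numeric(1)))
  out <- tibble::tibble(mean = mean(vals), sd = stats::sd(vals), reps = reps,
                        removal_fraction = removal_fraction, n_nodes = n)
  attr(out, "values") <- vals
  out
}

#' Stage-stratified and pooled networks
#'
#' Builds one network per stage group (defaults: early D1-D14, middle
#' D28-D42, late D60-D72) plus a pooled network over all samples of the
#' treatment, each on the same feature set so that complexity metrics are
#' comparable.
#'
#' @param quant Absolute-abundance tibble.
#' @param metadata Sample metadata.
#' @param treatment Treatment whose samples are used.
#' @param features Feature set (typically [core_features()] output).
#' @param stage_groups Named list mapping group label to stage days.
#' @param ... Passed to [build_network()].
#' @return Tibble (`stage_group`, `n_samples`, `n_edges`,
#'   `average_degree`) with the `co_network` objects in a `network`
#'   list-column; the pooled network has stage group `"pooled"`.
#' @export
build_stage_networks <- function(quant, metadata, treatment, features,
                                 stage_groups = list(
                                   "D1-D14" = c(1, 4, 7, 14),
                                   "D28-D42" = c(28, 42),
                                   "D60-D72" = c(60, 72)),
                                 ...) {
  check_metadata(metadata)
  md <- dplyr::filter(metadata, .data$treatment == !!treatment)
  groups <- c(stage_groups, list(pooled = sort(unique(md$stage_day))))
  purrr::map_dfr(names(groups), function(gname) {
    ids <- md$sample_id[md$stage_day %in% groups[[gname]]]
    sub <- dplyr::filter(quant, .data$sample_id %in% ids)
    net <- build_network(spearman_edges(sub, features), ...)
    tibble::tibble(stage_group = gname, n_samples = length(ids),
                   n_edges = net$metrics$n_edges,
                   average_degree = net$metrics$average_degree,
                   network = list(net))
  })
}
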