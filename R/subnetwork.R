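#' Extract the subnetwork induced by a gene list at an edge-weight cutoff
#'
#' Takes the selected genes and, among them, only the linkages whose weight
#' is strictly greater than `min_weight` (default 0.2 on the normalized
#' \[0, 1\] scale). Selected genes present in the network but left without a
#' passing edge are retained as isolated nodes; selected genes absent from
#' the network are ignored.
#'
#' @param network Normalized edge tibble ([normalize_edge_weights()]).
#' @param genes Character vector of gene symbols (e.g. from
#'   [select_influenced()]).
#' @param min_weight Strict edge-weight cut, default 0.2.
#' @param de_genes Optional DE tibble (human symbols) used to flag which
#'   subnetwork nodes are themselves differentially expressed.
#' @return A `subnetwork` object: list with `nodes` (tibble `symbol`,
#'   `is_de`), `edges` (tibble `gene_a`, `gene_b`, `weight`) and
#'   `min_weight`.
#' @export
extract_subnetwork <- function(network, genes, min_weight = 0.2,
                               de_genes = NULL) {
  keep <- sort(intersect(unique(genes), network_nodes(network)))
  edges <- network |>
    dplyr::filter(.data$gene_a %in% keep, .data$gene_b %in% keep,
                  .data$weight > min_weight)
  de_syms <- if (is.null(de_genes)) character() else de_genes$symbol
  structure(
    list(
      nodes = tibble(symbol = keep, is_de = keep %in% de_syms),
      edges = edges,
      min_weight = min_weight
    ),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Influenced subnetwork: ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " links (edge weight > ", x$min_weight, ")\n",
      sep = "")
  cat("  DE nodes: ", sum(x$nodes$is_de), "\n", sep = "")
  invisible(x)
}

as_igraph <- function(sub) {
  igraph::graph_from_data_frame(
    sub$edges, directed = FALSE,
    vertices = data.frame(name = sub$nodes$symbol)
  )
}

#' Connected components of a subnetwork
#'
#' @param sub A `subnetwork` from [extract_subnetwork()].
#' @return A list of character vectors (each sorted), ordered by decreasing
#'   component size with ties broken alphabetically by smallest member.
#' @export
subnetwork_components <- function(sub) {
  if (nrow(sub$nodes) == 0) return(list())
  comp <- igraph::components(as_igraph(sub))
  parts <- split(names(comp$membership), comp$membership)
  parts <- lapply(parts, function(x) sort(unname(x)))
  ord <- order(-lengths(parts), vapply(parts, `[`, "", 1))
  unname(parts[ord])
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/W - (s_c / 2W)^2 ]` with `w_in(c)` the intra-cluster
#' edge weight, `s_c` the summed node strength of cluster `c` and `W` the
#' total edge weight; the objective the annealing clusterer maximizes.
#'
#' @param sub A `subnetwork`.
#' @param assignment Integer vector of cluster ids, one per `sub$nodes` row.
#' @return The modularity, 0 for an edgeless subnetwork.
#' @export
weighted_modularity <- function(sub, assignment) {
  stopifnot(length(assignment) == nrow(sub$nodes))
  W <- sum(sub$edges$weight)
  if (W == 0) return(0)
  z <- setNames(assignment, sub$nodes$symbol)
  w_in <- sum(sub$edges$weight[z[sub$edges$gene_a] == z[sub$edges$gene_b]])
  strength <- setNames(rep(0, nrow(sub$nodes)), sub$nodes$symbol)
  add_a <- tapply(sub$edges$weight, sub$edges$gene_a, sum)
  add_b <- tapply(sub$edges$weight, sub$edges$gene_b, sum)
  strength[names(add_a)] <- strength[names(add_a)] + add_a
  strength[names(add_b)] <- strength[names(add_b)] + add_b
  s_c <- tapply(strength, assignment, sum)
  w_in / W - sum((s_c / (2 * W))^2)
}

#' Annealing schedule parameters
#'
#' @param t0 Starting temperature (default 1).
#' @param cooling Geometric cooling factor per temperature step (default
#'   0.995).
#' @param moves_per_node Proposed single-node moves per temperature, per node
#'   (default 100, i.e. `100 * n` proposals each step).
#' @param t_min Stop when the temperature falls below this (default 1e-4).
#' @param patience Stop after this many consecutive temperatures without a
#'   best-so-far improvement (default 50).
#' @return A list of schedule parameters for [sa_cluster()].
#' @export
sa_control <- function(t0 = 1.0, cooling = 0.995, moves_per_node = 100,
                       t_min = 1e-4, patience = 50) {
  stopifnot(t0 > 0, cooling > 0, cooling < 1, moves_per_node >= 1,
            t_min > 0, patience >= 1)
  list(t0 = t0, cooling = cooling, moves_per_node = moves_per_node,
       t_min = t_min, patience = patience)
}

#' Decompose a subnetwork into dense clusters by simulated annealing
#'
#' Maximizes weighted modularity over node partitions with single-node
#' reassignment moves and Metropolis acceptance `exp(dQ/T)` under a geometric
#' cooling schedule, returning the best partition seen. With `k` supplied the
#' partition uses exactly that many cluster labels (empty labels may remain
#' unused); with `k` free, clusters start as singletons, empty clusters are
#' pruned, and any cluster spanning two connected components is split (which
#' never lowers Q). Cluster ids are relabelled 1..k in order of each
#' cluster's alphabetically smallest member, so results are reproducible for
#' a fixed seed and schedule.
#'
#' @param sub A `subnetwork` from [extract_subnetwork()].
#' @param k Optional fixed number of cluster labels; default free.
#' @param seed Integer RNG seed; the run is deterministic given
#'   `seed` + schedule.
#' @param control Schedule from [sa_control()].
#' @return An object of class `sa_clustering`: list with `assignment`
#'   (tibble `symbol`, `cluster`, `is_de`), `k`, `modularity` (recomputed
#'   from the final assignment), `trace` (tibble `step`, `temperature`,
#'   `best_q`), and `seed`.
#' @examples
#' cfg <- synth_config(seed = 1)
#' net <- simulate_network(cfg)
#' sub <- extract_subnetwork(normalize_edge_weights(net$network),
#'                           network_nodes(net$network), min_weight = 0)
#' cl <- sa_cluster(sub, seed = 7)
#' glance(cl)
#' @export
sa_cluster <- function(sub, k = NULL, seed = 1L, control = sa_control()) {
  n <- nrow(sub$nodes)
  if (n == 0) abort("subnetwork has no nodes")
  if (nrow(sub$edges) == 0) {
    if (n > 1) warn("subnetwork has no edges: every node is its own cluster")
    return(new_sa_clustering(sub, seq_len(n), trace = empty_trace(),
                             seed = seed))
  }

  idx <- setNames(seq_len(n) - 1L, sub$nodes$symbol)
  from <- unname(idx[sub$edges$gene_a])
  to <- unname(idx[sub$edges$gene_b])
  free_k <- is.null(k)
  if (free_k) {
    k_max <- n
    init <- seq_len(n) - 1L
  } else {
    stopifnot(k >= 1, k <= n)
    k_max <- as.integer(k)
    init <- (seq_len(n) - 1L) %% k_max
  }

  set.seed(seed)
  res <- sa_anneal_cpp(n, from, to, sub$edges$weight, init, k_max,
                       control$t0, control$cooling,
                       as.integer(control$moves_per_node * n),
                       control$t_min, as.integer(control$patience))
  z <- res$assignment + 1L

  if (free_k) {
    # splitting a cluster across components never decreases Q
    comp <- igraph::components(as_igraph(sub))$membership[sub$nodes$symbol]
    z <- as.integer(factor(paste(z, comp)))
  }

  trace <- tibble(step = seq_along(res$trace_q),
                  temperature = res$trace_t, best_q = res$trace_q)
  new_sa_clustering(sub, z, trace = trace, seed = seed)
}

empty_trace <- function() {
  tibble(step = integer(), temperature = double(), best_q = double())
}

new_sa_clustering <- function(sub, z, trace, seed) {
  # contiguous ids ordered by each cluster's alphabetically smallest member
  first <- tapply(sub$nodes$symbol, z, min)
  relabel <- setNames(seq_along(first), names(first)[order(first)])
  z <- unname(relabel[as.character(z)])
  structure(
    list(
      assignment = tibble(symbol = sub$nodes$symbol, cluster = z,
                          is_de = sub$nodes$is_de),
      k = max(z),
      modularity = weighted_modularity(sub, z),
      trace = trace,
      seed = seed
    ),
    class = "sa_clustering"
  )
}

#' @export
print.sa_clustering <- function(x, ...) {
  cat("Simulated-annealing clustering: ", nrow(x$assignment), " nodes in ",
      x$k, " cluster(s), Q = ", format(x$modularity, digits = 4),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @describeIn sa_cluster Per-node cluster assignment as a tibble.
#' @param x An `sa_clustering` object.
#' @param ... Unused.
#' @method tidy sa_clustering
#' @export
tidy.sa_clustering <- function(x, ...) x$assignment

#' @describeIn sa_cluster One-row summary: nodes, clusters, modularity.
#' @method glance sa_clustering
#' @export
glance.sa_clustering <- function(x, ...) {
  tibble(n_nodes = nrow(x$assignment), k = x$k, modularity = x$modularity,
         n_de = sum(x$assignment$is_de), seed = x$seed)
}
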