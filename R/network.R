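#' Read a weighted gene association network from an edge list
#'
#' Reads a three-column tab-delimited edge list (`gene_a`, `gene_b`,
#' `weight`), the format of functional linkage networks distributed as flat
#' files. The graph is undirected and simple: an edge listed in both
#' orientations (or repeated) keeps its maximum weight, and self-loops are
#' dropped with a message (the scoring model fixes the self-linkage at 1, so
#' stored self-edges carry no information).
#'
#' @param path Edge-list file; a header row is detected and skipped when the
#'   third field of the first line is not numeric.
#' @return A tibble of edges with columns `gene_a`, `gene_b`, `weight`,
#'   canonically oriented so `gene_a < gene_b`.
#' @export
read_network <- function(path) {
  raw <- readr::read_tsv(path,
                         col_names = c("gene_a", "gene_b", "weight"),
                         col_types = "ccc", progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  weight = double()))
  }
  if (is.na(suppressWarnings(as.numeric(raw$weight[1])))) raw <- raw[-1, ]
  w <- suppressWarnings(as.numeric(raw$weight))
  bad <- which(is.na(w) | is.na(raw$gene_a) | is.na(raw$gene_b) | w <= 0)
  if (length(bad) > 0) {
    abort(paste0("malformed edge at line ", bad[1], " of '", path,
                 "': need gene_a<TAB>gene_b<TAB>positive weight"))
  }
  edges <- tibble(gene_a = raw$gene_a, gene_b = raw$gene_b, weight = w)
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    inform(paste0(sum(loops), " self-loop(s) dropped"))
    edges <- edges[!loops, ]
  }
  canonicalize_edges(edges)
}

# orient gene_a < gene_b and collapse duplicates to the max weight
canonicalize_edges <- function(edges) {
  edges |>
    dplyr::mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
    dplyr::transmute(gene_a = .data$a, gene_b = .data$b,
                     weight = .data$weight) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Gene symbols present in a network
#'
#' @param network Edge tibble from [read_network()].
#' @return Sorted character vector of node symbols.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$gene_a, network$gene_b)))
}

#' Min-max normalize edge weights to the unit interval
#'
#' Rescales all edge weights by `(w - min) / (max - min)` so the smallest
#' weight becomes 0 and the largest 1, putting networks with arbitrary
#' positive confidence scales on the \[0, 1\] scale the influence score and
#' the 0.2 subnetwork cutoff assume. If all weights are equal the range is
#' degenerate and every edge gets weight 1, preserving connectivity.
#' Idempotent on input already spanning \[0, 1\].
#'
#' @inheritParams network_nodes
#' @return The edge tibble with rescaled `weight`.
#' @export
normalize_edge_weights <- function(network) {
  if (nrow(network) == 0) {
    warn("empty network: nothing to normalize")
    return(network)
  }
  rng <- range(network$weight)
  if (rng[1] == rng[2]) {
    network$weight <- 1
  } else {
    network$weight <- (network$weight - rng[1]) / (rng[2] - rng[1])
  }
  network
}

#' Node-weight vector for a DE gene set over a network
#'
#' Builds the per-node weight vector of the influence score: the absolute
#' log2 ratio for differentially expressed genes present in the network and
#' zero everywhere else. DE genes absent from the network are reported and
#' contribute nothing (no proxy nodes are created).
#'
#' @inheritParams network_nodes
#' @param de_genes Human-symbol DE tibble ([map_to_human()] output, or any
#'   tibble with `symbol` and `node_weight` columns).
#' @return A tibble with one row per network node: `symbol`, `weight`.
#' @export
node_weights <- function(network, de_genes) {
  nodes <- network_nodes(network)
  absent <- setdiff(de_genes$symbol, nodes)
  if (length(absent) > 0) {
    inform(paste0(length(absent), " DE gene(s) not in the network: ",
                  paste(head(absent, 10), collapse = ", ")))
  }
  w <- setNames(rep(0, length(nodes)), nodes)
  present <- de_genes$symbol %in% nodes
  w[de_genes$symbol[present]] <- de_genes$node_weight[present]
  tibble(symbol = nodes, weight = unname(w))
}

#' Network-effect score of every gene
#'
#' For each network gene i the score is the weighted sum of
#' differential-expression node weights over its linkages,
#' `S_i = sum_j w_j W_ij`, where `w_j` is `|log2 ratio|` for DE genes and 0
#' otherwise, `W_ij` is the edge weight between i and j (0 for non-adjacent
#' pairs), and the self-linkage `W_ii` is fixed at 1 — so a DE gene always
#' scores at least its own weight. Higher scores mark genes more strongly
#' influenced by the DE set. Computed by sparse accumulation over the edge
#' list; the result does not depend on edge order.
#'
#' @inheritParams network_nodes
#' @param weights Per-node weight tibble from [node_weights()] (must cover
#'   exactly the network's nodes).
#' @return A tibble (`symbol`, `score`) sorted by decreasing score, ties
#'   alphabetical.
#' @export
network_effect_scores <- function(network, weights) {
  nodes <- network_nodes(network)
  if (!setequal(weights$symbol, nodes) || anyDuplicated(weights$symbol)) {
    abort("`weights` must cover exactly the network's nodes, once each")
  }
  w <- setNames(weights$weight, weights$symbol)
  s <- w  # self term, W_ii = 1
  if (nrow(network) > 0) {
    ca <- tapply(w[network$gene_b] * network$weight, network$gene_a, sum)
    cb <- tapply(w[network$gene_a] * network$weight, network$gene_b, sum)
    s[names(ca)] <- s[names(ca)] + ca
    s[names(cb)] <- s[names(cb)] + cb
  }
  tibble(symbol = names(s), score = unname(s)) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$symbol)
}

#' Select genes significantly influenced by the DE set
#'
#' Genes whose network-effect score is strictly greater than `threshold`,
#' ordered by decreasing score with alphabetical tie-break. The default 150
#' is calibrated to the full-scale human functional linkage network; for
#' other networks pick a scale-appropriate value or a score quantile.
#'
#' @param scores Tibble from [network_effect_scores()].
#' @param threshold Strict lower score cut (default 150).
#' @return Character vector of gene symbols.
#' @export
select_influenced <- function(scores, threshold = 150) {
  scores |>
    dplyr::filter(.data$score > threshold) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$symbol) |>
    dplyr::pull(.data$symbol)
}

#' Write a score table or edge list to TSV
#'
#' @param x Tibble to write.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a network edge list to TSV
#'
#' Three columns (`gene_a`, `gene_b`, `weight`), no header, the format
#' [read_network()] reads.
#'
#' @inheritParams network_nodes
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  readr::write_tsv(network, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
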