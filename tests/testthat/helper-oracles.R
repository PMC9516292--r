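# Independent oracles and small fixtures shared across tests.

# Dense all-pairs evaluation of the influence score: build the full weight
# matrix (diagonal fixed at 1, zero off-diagonal for non-adjacent pairs) and
# take the matrix-vector product with the node-weight vector. Quadratic and
# deliberately naive -- the reference the sparse accumulation is checked
# against.
dense_score_oracle <- function(network, weights) {
  nodes <- sort(unique(c(network$gene_a, network$gene_b)))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(network))) {
    a <- network$gene_a[e]; b <- network$gene_b[e]
    W[a, b] <- network$weight[e]
    W[b, a] <- network$weight[e]
  }
  diag(W) <- 1
  w <- stats::setNames(weights$weight, weights$symbol)[nodes]
  drop(W %*% w)
}

# Erdos-Renyi-ish random weighted network plus a random DE subset.
random_network_case <- function(n_nodes, n_edges, n_de, seed) {
  set.seed(seed)
  nodes <- sprintf("g%03d", seq_len(n_nodes))
  pairs <- t(utils::combn(n_nodes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  network <- tibble::tibble(
    gene_a = nodes[pairs[pick, 1]],
    gene_b = nodes[pairs[pick, 2]],
    weight = round(stats::runif(length(pick), 0.05, 1), 4)
  )
  de <- tibble::tibble(
    symbol = sample(nodes, n_de),
    log2_ratio = round(stats::runif(n_de, -4, 4), 3)
  )
  de$node_weight <- abs(de$log2_ratio)
  de$direction <- ifelse(de$log2_ratio > 0, "up", "down")
  list(network = network, de = de)
}

# 3-node path fixture: a -(0.5)- b -(0.25)- c, DE = {a, weight 2}
path3_fixture <- function() {
  list(
    network = tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "c"),
                             weight = c(0.5, 0.25)),
    de = tibble::tibble(symbol = "a", log2_ratio = 2, node_weight = 2,
                        direction = "up")
  )
}

# two disconnected 5-cliques, all edge weights 1
two_cliques_subnetwork <- function() {
  clique <- function(prefix) {
    pairs <- t(utils::combn(5, 2))
    tibble::tibble(gene_a = sprintf("%s%d", prefix, pairs[, 1]),
                   gene_b = sprintf("%s%d", prefix, pairs[, 2]),
                   weight = 1)
  }
  net <- dplyr::bind_rows(clique("a"), clique("b"))
  extract_subnetwork(net, network_nodes(net), min_weight = 0)
}

# planted-partition graph with known labels (weights already in [0, 1])
planted_partition_case <- function(seed, k = 4, per = 10,
                                   p_in = 0.8, p_out = 0.05,
                                   w_in = c(0.8, 1), w_out = c(0.05, 0.15)) {
  net <- simulate_network(synth_config(
    seed = seed, n_up = 0, n_down = 0, n_shared_orthologs = 0,
    n_modules = k, module_size = per, intra_p = p_in, inter_p = p_out,
    intra_weight_range = w_in, inter_weight_range = w_out
  ))
  sub <- extract_subnetwork(net$network, net$truth$membership$symbol,
                            min_weight = 0)
  labels <- net$truth$membership$module[
    match(sub$nodes$symbol, net$truth$membership$symbol)]
  list(sub = sub, labels = labels)
}

nmi <- function(a, b) igraph::compare(a, b, method = "nmi")

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
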