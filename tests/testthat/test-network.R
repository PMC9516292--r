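test_that("read_network dedups to max weight, drops self-loops, errors well", {
  p <- write_lines_tmp(c("a\tb\t0.4", "b\ta\t0.6", "b\tc\t0.25",
                         "c\tc\t0.9"))
  expect_message(net <- read_network(p), "self-loop")
  expect_equal(nrow(net), 2)
  expect_equal(net$weight[net$gene_a == "a" & net$gene_b == "b"], 0.6)

  expect_equal(nrow(read_network(write_lines_tmp(character()))), 0)
  expect_error(read_network(write_lines_tmp(c("a\tb\t0.4", "a\tc\tx"))),
               "line 2")
  # header rows are tolerated
  expect_equal(nrow(read_network(write_lines_tmp(
    c("gene_a\tgene_b\tweight", "a\tb\t0.4")))), 1)
})

test_that("min-max normalization maps weights onto [0,1] and is idempotent", {
  net <- tibble::tibble(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
                        weight = c(2, 4, 6))
  norm <- normalize_edge_weights(net)
  expect_equal(sort(norm$weight), c(0, 0.5, 1))
  expect_equal(normalize_edge_weights(norm)$weight, norm$weight)

  same <- tibble::tibble(gene_a = "a", gene_b = "b", weight = 7)
  expect_equal(normalize_edge_weights(same)$weight, 1)
  expect_warning(normalize_edge_weights(net[0, ]), "empty")
})

test_that("node weights are |log2 ratio| on DE genes and zero elsewhere", {
  fx <- path3_fixture()
  expect_equal(node_weights(fx$network, fx$de[0, ])$weight, c(0, 0, 0))
  de <- tibble::tibble(symbol = "c", log2_ratio = -log2(10.4),
                       node_weight = log2(10.4), direction = "down")
  w <- node_weights(fx$network, de)
  expect_equal(w$weight[w$symbol == "c"], 3.3785, tolerance = 1e-4)
  ghost <- dplyr::mutate(de, symbol = "zz")
  expect_message(w2 <- node_weights(fx$network, ghost), "not in the network")
  expect_equal(w2$weight, c(0, 0, 0))
})

test_that("hand-worked path fixture scores match the influence formula", {
  fx <- path3_fixture()
  s <- network_effect_scores(fx$network, node_weights(fx$network, fx$de))
  expect_equal(s$score[match(c("a", "b", "c"), s$symbol)], c(2, 1.0, 0))
})

test_that("sparse accumulation equals the dense all-pairs oracle", {
  for (seed in 1:20) {
    case <- random_network_case(n_nodes = sample(5:50, 1),
                                n_edges = sample(4:100, 1),
                                n_de = sample(1:5, 1), seed = seed)
    w <- node_weights(case$network, case$de)
    s <- network_effect_scores(case$network, w)
    oracle <- dense_score_oracle(case$network, w)
    expect_equal(s$score[match(names(oracle), s$symbol)], unname(oracle),
                 tolerance = 1e-9)
  }
})

test_that("scores satisfy self-term, monotonicity and normalization bounds", {
  case <- random_network_case(30, 60, 5, seed = 99)
  net <- normalize_edge_weights(case$network)
  w <- node_weights(net, case$de)
  s <- network_effect_scores(net, w)
  # every score at least the gene's own weight, at most the total DE weight
  expect_true(all(s$score + 1e-12 >=
                    w$weight[match(s$symbol, w$symbol)]))
  expect_true(all(s$score <= sum(w$weight) + 1e-12))

  # adding an edge from a DE gene never lowers the other endpoint's score
  de_gene <- case$de$symbol[1]
  target <- setdiff(s$symbol, c(de_gene, net$gene_b[net$gene_a == de_gene],
                                net$gene_a[net$gene_b == de_gene]))[1]
  net2 <- dplyr::bind_rows(net, tibble::tibble(gene_a = de_gene,
                                               gene_b = target,
                                               weight = 0.5))
  s2 <- network_effect_scores(net2, node_weights(net2, case$de))
  expect_gte(s2$score[s2$symbol == target], s$score[s$symbol == target])

  # increasing a node weight never decreases any score
  de_up <- dplyr::mutate(case$de,
                         node_weight = node_weight + 1)
  s3 <- network_effect_scores(net, node_weights(net, de_up))
  expect_true(all(s3$score[match(s$symbol, s3$symbol)] >= s$score - 1e-12))
})

test_that("degree-0 DE gene scores exactly its node weight", {
  net <- tibble::tibble(gene_a = c("a", "x"), gene_b = c("b", "y"),
                        weight = c(0.5, 0.8))
  de <- tibble::tibble(symbol = "x", log2_ratio = 3.3785,
                       node_weight = 3.3785, direction = "up")
  # x has one edge to y; isolate it by zero weight on the DE side instead:
  net0 <- tibble::tibble(gene_a = "a", gene_b = "b", weight = 0.5)
  de0 <- tibble::tibble(symbol = "a", log2_ratio = 1.5, node_weight = 1.5,
                        direction = "up")
  s <- network_effect_scores(net0, node_weights(net0, de0))
  expect_equal(s$score[s$symbol == "a"], 1.5)  # b not DE: only self term
})

test_that("select_influenced uses a strict cut with deterministic order", {
  scores <- tibble::tibble(symbol = c("a", "b", "c"),
                           score = c(151, 150, 149.9))
  expect_identical(select_influenced(scores), "a")
  expect_identical(select_influenced(scores, threshold = 0), c("a", "b", "c"))
  ties <- tibble::tibble(symbol = c("z", "m"), score = c(5, 5))
  expect_identical(select_influenced(ties, 0), c("m", "z"))
  none <- tibble::tibble(symbol = "a", score = 0)
  expect_identical(select_influenced(none), character(0))
})

test_that("scores error on a weight vector that mismatches the network", {
  fx <- path3_fixture()
  w <- tibble::tibble(symbol = c("a", "b"), weight = c(1, 1))
  expect_error(network_effect_scores(fx$network, w), "cover")
})
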