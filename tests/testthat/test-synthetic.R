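test_that("identical configurations produce byte-identical outputs", {
  cfg <- synth_config(seed = 9, n_genes = 300, n_up = 5, n_down = 8,
                      n_null_psig = 30, n_untested = 5,
                      n_shared_orthologs = 2, module_size = 20)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  generate_synthetic_data(d1, cfg)
  generate_synthetic_data(d2, cfg)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("every emitted file parses with its reader", {
  cfg <- synth_config(seed = 2, n_genes = 300, n_up = 5, n_down = 8,
                      n_null_psig = 30, n_untested = 5,
                      n_shared_orthologs = 2, module_size = 20)
  d <- tempfile()
  out <- generate_synthetic_data(d, cfg)
  expect_equal(nrow(read_diff(out$paths$diff)), 300)
  net <- read_network(out$paths$network)
  expect_gt(nrow(net), 0)
  expect_true(all(network_nodes(net) %in%
                    names(out$truth$network$membership)))
  expect_gt(nrow(read_ortholog_map(out$paths$orthologs)), 0)
  expect_gt(nrow(read_gmt(out$paths$gmt)), 0)
  expect_equal(length(read_fasta(out$paths$fasta)), 1)
  expect_true(jsonlite::validate(paste(readLines(out$paths$truth),
                                       collapse = "")))
})

test_that("the DE filter recovers exactly the planted genes", {
  cfg <- synth_config(seed = 4)
  gen <- simulate_de_table(cfg)
  path <- tempfile(fileext = ".diff")
  write_diff(gen$table, path)
  rec <- read_diff(path)
  de <- suppressMessages(
    filter_de(rec, fold_threshold = min(cfg$up_fold_range[1],
                                        cfg$down_fold_range[1])))
  expect_setequal(de$symbol, gen$truth$de)
  expect_equal(nrow(de), cfg$n_up + cfg$n_down)
  expect_setequal(de$symbol[de$direction == "up"], gen$truth$up)
  expect_setequal(de$symbol[de$direction == "down"], gen$truth$down)
  expect_equal(count_significant(rec), gen$truth$n_p_significant)

  empty <- simulate_de_table(synth_config(seed = 1, n_genes = 50, n_up = 0,
                                          n_down = 0, n_null_psig = 5,
                                          n_untested = 0,
                                          n_shared_orthologs = 0))
  p2 <- tempfile(); write_diff(empty$table, p2)
  expect_equal(nrow(filter_de(read_diff(p2), 2.7)), 0)
})

test_that("planted down-regulated folds follow the configured range", {
  cfg <- synth_config(seed = 6)
  truth <- simulate_de_table(cfg)$truth
  downs <- truth$folds$fold[truth$folds$symbol %in% truth$down]
  expect_true(all(downs >= cfg$down_fold_range[1] &
                    downs <= cfg$down_fold_range[2]))
  ups <- truth$folds$fold[truth$folds$symbol %in% truth$up]
  expect_true(all(ups >= cfg$up_fold_range[1] & ups <= cfg$up_fold_range[2]))
})

test_that("ortholog collapse yields the configured distinct human count", {
  cfg <- synth_config(seed = 5)
  gen <- simulate_de_table(cfg)
  path <- tempfile(); write_diff(gen$table, path)
  de <- suppressMessages(filter_de(read_diff(path), fold_threshold = 2.7))
  human <- map_to_human(de, simulate_ortholog_map(cfg))
  expect_equal(nrow(human),
               cfg$n_up + cfg$n_down - cfg$n_shared_orthologs)  # 85 -> 75
})

test_that("a single-module network is one connected component", {
  net <- simulate_network(synth_config(seed = 3, n_up = 2, n_down = 3,
                                       n_shared_orthologs = 0,
                                       n_modules = 1, module_size = 30,
                                       intra_p = 0.4))
  sub <- extract_subnetwork(net$network, net$truth$membership$symbol, 0)
  expect_length(subnetwork_components(sub), 1)
})

test_that("DE genes concentrate the top scores in their module", {
  cfg <- synth_config(seed = 8)
  net <- simulate_network(cfg)
  de_human <- simulate_de_table(cfg)$truth$de_human
  de <- tibble::tibble(symbol = de_human, log2_ratio = 2.5,
                       node_weight = 2.5, direction = "down")
  network <- normalize_edge_weights(net$network)
  scores <- suppressMessages(
    network_effect_scores(network, node_weights(network, de)))
  top50 <- scores$symbol[1:50]
  module_of <- setNames(net$truth$membership$module,
                        net$truth$membership$symbol)
  expect_gte(mean(module_of[top50] == cfg$de_module), 0.9)
})

test_that("planted promoter features are found by the scanners", {
  cfg <- synth_config(seed = 12)
  prom <- simulate_promoter(cfg)
  feats <- prom$truth$features
  gres <- feats[feats$type == "gre", ]
  hits <- scan_motif(prom$seqs, cfg$gre_consensus, threshold = 1)
  expect_gte(nrow(hits), cfg$n_gre_sites)
  for (i in seq_len(nrow(gres))) {
    expect_true(any(hits$start == gres$start[i] & hits$strand == "+"))
  }
  cas <- prom$truth$cassettes[[1]]
  amp <- in_silico_pcr(prom$seqs, cas$forward, cas$reverse)
  expect_true(cas$amplicon_length %in% amp$length)
  expect_equal(cas$amplicon_length, 17 + 95 + 22)
})

test_that("a featureless promoter has no high-threshold motif hits", {
  cfg <- synth_config(seed = 13, n_gre_sites = 0,
                      primer_cassettes = list())
  prom <- simulate_promoter(cfg)
  expect_equal(nrow(prom$truth$features), 0)
  hits <- scan_motif(prom$seqs, "GGTACANNNTGTTCT", threshold = 1)
  expect_lte(nrow(hits), 1)  # exact background hits are ~Poisson(0.01)
})

test_that("the pipeline recovers the planted module across seeds", {
  hits <- vapply(1:10, function(seed) {
    cfg <- synth_config(seed = 700 + seed, n_genes = 800, n_up = 5,
                        n_down = 10, n_shared_orthologs = 3,
                        n_null_psig = 80, module_size = 30)
    net <- simulate_network(cfg)
    pws <- simulate_pathways(cfg, membership = net$truth$membership)
    de_human <- simulate_de_table(cfg)$truth$de_human
    de <- tibble::tibble(symbol = de_human, log2_ratio = 2.5,
                         node_weight = 2.5, direction = "down")
    network <- normalize_edge_weights(net$network)
    scores <- suppressMessages(
      network_effect_scores(network, node_weights(network, de)))
    top <- select_influenced(scores,
                             quantile(scores$score, cfg$influence_quantile))
    ranked <- rank_pathways(pathway_analysis(scores, top, pws$pathways))
    identical(ranked$pathway[1], pws$truth$de_pathway)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("infeasible configurations error", {
  expect_error(synth_config(n_genes = 10), "n_null_psig|n_up")
  expect_error(synth_config(module_size = 10), "module")
  expect_error(
    simulate_promoter(synth_config(seed = 1, promoter_length = 50)),
    "fit")
})
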