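#' Run the full influence analysis from input files
#'
#' End-to-end convenience wrapper: read and filter the DE table, map mouse
#' symbols to human orthologs, normalize the association network, compute
#' network-effect scores, select influenced genes, extract and cluster the
#' influenced subnetwork, and score/rank pathways. Each stage is also
#' available as an individual function; this wires them together with the
#' study's thresholds as defaults.
#'
#' @param diff_file Cuffdiff-style `.diff` table ([read_diff()]).
#' @param network_file Weighted edge list ([read_network()]).
#' @param ortholog_file Two-column mouse-to-human symbol table
#'   ([read_ortholog_map()]); `NULL` skips mapping (DE symbols used as-is).
#' @param gmt_file Pathway gene sets in GMT format ([read_gmt()]); `NULL`
#'   skips the pathway stage.
#' @param fold_threshold,q_threshold DE filter cuts ([filter_de()]).
#' @param score_threshold Absolute influenced-gene score cut
#'   ([select_influenced()]); default 150, the full-scale linkage-network
#'   calibration.
#' @param score_quantile If non-`NULL`, overrides `score_threshold` with
#'   this quantile of the score distribution — the right choice for networks
#'   on other scales, including synthetic ones.
#' @param edge_min Subnetwork edge-weight cut ([extract_subnetwork()]).
#' @param k Optional fixed cluster count for [sa_cluster()].
#' @param seed Seed for the annealing run.
#' @param pathway_annotation Optional pathway annotation table or file
#'   (see [read_gmt()]).
#' @param control Annealing schedule ([sa_control()]).
#' @return A list with elements `de_genes`, `human_de`, `scores`,
#'   `score_threshold`, `influenced`, `subnetwork`, `components`,
#'   `clustering`, and (when `gmt_file` is given) `pathway_results` and
#'   `ranked_pathways`.
#' @export
run_influence_pipeline <- function(diff_file, network_file,
                                   ortholog_file = NULL, gmt_file = NULL,
                                   fold_threshold = 3, q_threshold = 0.05,
                                   score_threshold = 150,
                                   score_quantile = NULL,
                                   edge_min = 0.2, k = NULL, seed = 1L,
                                   pathway_annotation = NULL,
                                   control = sa_control()) {
  for (f in c(diff_file, network_file, ortholog_file, gmt_file)) {
    if (!file.exists(f)) {
      abort(paste0("input file not found: '", f, "'"))
    }
  }

  records <- read_diff(diff_file)
  de_genes <- filter_de(records, fold_threshold = fold_threshold,
                        q_threshold = q_threshold)
  human_de <- if (is.null(ortholog_file)) {
    de_genes
  } else {
    map_to_human(de_genes, read_ortholog_map(ortholog_file))
  }

  network <- normalize_edge_weights(read_network(network_file))
  scores <- network_effect_scores(network, node_weights(network, human_de))
  if (!is.null(score_quantile)) {
    score_threshold <- unname(quantile(scores$score, score_quantile))
  }
  influenced <- select_influenced(scores, threshold = score_threshold)

  sub <- extract_subnetwork(network, influenced, min_weight = edge_min,
                            de_genes = human_de)
  components <- subnetwork_components(sub)
  clustering <- if (nrow(sub$nodes) > 0) {
    sa_cluster(sub, k = k, seed = seed, control = control)
  } else NULL

  out <- list(
    de_genes = de_genes, human_de = human_de, scores = scores,
    score_threshold = score_threshold, influenced = influenced,
    subnetwork = sub, components = components, clustering = clustering
  )
  if (!is.null(gmt_file)) {
    pathways <- read_gmt(gmt_file, annotation = pathway_annotation)
    out$pathway_results <- pathway_analysis(scores, influenced, pathways)
    out$ranked_pathways <- rank_pathways(out$pathway_results)
  }
  out
}
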