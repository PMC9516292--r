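#' Read pathway gene sets from a GMT file
#'
#' Standard gene-matrix-transposed format: one pathway per line, tab
#' separated, `id<TAB>description<TAB>gene1<TAB>gene2...`. Parsed with
#' [fgsea::gmtPathways()] and returned long.
#'
#' @param path GMT file.
#' @param annotation Optional tibble (or path to a tab-delimited file with a
#'   header) carrying per-pathway annotation columns, first column `pathway`;
#'   typically the two hierarchical pathway-class labels. Joined onto the
#'   result as-is.
#' @return A long tibble with columns `pathway`, `symbol` (one row per
#'   pathway-gene pair) plus any annotation columns.
#' @export
read_gmt <- function(path, annotation = NULL) {
  sets <- fgsea::gmtPathways(path)
  out <- tibble(
    pathway = rep(names(sets), lengths(sets)),
    symbol = unlist(sets, use.names = FALSE)
  ) |>
    dplyr::distinct()
  if (!is.null(annotation)) {
    if (is.character(annotation)) {
      annotation <- readr::read_tsv(annotation, show_col_types = FALSE,
                                    progress = FALSE)
    }
    names(annotation)[1] <- "pathway"
    out <- dplyr::left_join(out, annotation, by = "pathway")
  }
  out
}

#' Write pathway gene sets to a GMT file
#'
#' @param pathways Long tibble (`pathway`, `symbol`), as from [read_gmt()].
#' @param path Output file.
#' @param descriptions Optional named character vector of per-pathway
#'   description fields; defaults to the pathway id.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path, descriptions = NULL) {
  sets <- split(pathways$symbol, pathways$pathway)
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions)) {
      descriptions[[id]]
    } else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Score pathways by the mean network-effect score of member genes
#'
#' A pathway's score is the arithmetic mean of `S_i` over its genes present
#' in the score table; genes absent from the network (no defined score) are
#' excluded from the mean and counted in `n_unscored`. A pathway with no
#' scored gene gets `mean_score` 0 and `no_scored_genes = TRUE`. Set
#' `absent_as_zero = TRUE` to instead count absent genes as score 0.
#'
#' @param scores Tibble from [network_effect_scores()].
#' @param pathways Long pathway tibble from [read_gmt()].
#' @param absent_as_zero Treat pathway genes missing from the score table as
#'   scoring 0 rather than excluding them (default `FALSE`).
#' @return A tibble with one row per pathway: `pathway`, `n_scored`,
#'   `n_unscored`, `mean_score`, `no_scored_genes`.
#' @export
pathway_scores <- function(scores, pathways, absent_as_zero = FALSE) {
  s <- setNames(scores$score, scores$symbol)
  pathways |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_scored = sum(.data$symbol %in% names(s)),
      n_unscored = sum(!.data$symbol %in% names(s)),
      mean_score = {
        v <- s[.data$symbol]
        if (absent_as_zero) v[is.na(v)] <- 0 else v <- v[!is.na(v)]
        if (length(v) == 0) 0 else mean(v)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(no_scored_genes = .data$n_scored == 0 & !absent_as_zero)
}

#' Hypergeometric enrichment of top-scored genes in pathways
#'
#' For each pathway, counts the overlap with the top-scored gene list and
#' tests over-representation with the one-sided hypergeometric upper tail
#' `P(X >= overlap)` (population: the gene universe; successes: pathway
#' genes in the universe; draws: the top list), Benjamini-Hochberg adjusted
#' across pathways. Zero overlap is reported as p = 1 exactly.
#'
#' @param top_genes Character vector of top-scored gene symbols, a subset of
#'   `universe`.
#' @param pathways Long pathway tibble from [read_gmt()].
#' @param universe Character vector of all genes considered (typically the
#'   network's node set).
#' @return A tibble: `pathway`, `total_genes` (pathway genes in universe),
#'   `mapped_genes` (overlap with `top_genes`), `enrichment_p`,
#'   `enrichment_q`.
#' @export
pathway_enrichment <- function(top_genes, pathways, universe) {
  top_genes <- unique(top_genes)
  if (!all(top_genes %in% universe)) {
    abort("`top_genes` must be a subset of `universe`")
  }
  n_univ <- length(unique(universe))
  n_draw <- length(top_genes)
  res <- pathways |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      total_genes = sum(unique(.data$symbol) %in% universe),
      mapped_genes = length(intersect(.data$symbol, top_genes)),
      .groups = "drop"
    )
  if (any(res$total_genes > n_univ)) {
    abort("universe smaller than a pathway: not a valid gene universe")
  }
  res |>
    dplyr::mutate(
      enrichment_p = ifelse(
        .data$mapped_genes == 0, 1,
        phyper(.data$mapped_genes - 1, .data$total_genes,
               n_univ - .data$total_genes, n_draw, lower.tail = FALSE)
      ),
      enrichment_q = p.adjust(.data$enrichment_p, method = "BH")
    )
}

#' Rank pathways by mean score among the significantly enriched
#'
#' The pathways called "significantly affected" are those both enriched with
#' top-scored genes (BH q strictly below `q_max`) and carrying the highest
#' mean member scores: the enrichment filter is applied first, then pathways
#' are sorted by decreasing `mean_score`, ties by decreasing `mapped_genes`
#' then pathway id.
#'
#' @param results Tibble combining [pathway_scores()] and
#'   [pathway_enrichment()] columns (see [pathway_analysis()]).
#' @param q_max Strict BH-adjusted enrichment cut, default 0.05.
#' @return The filtered, ordered tibble with a leading `rank` column.
#' @export
rank_pathways <- function(results, q_max = 0.05) {
  results |>
    dplyr::filter(.data$enrichment_q < q_max) |>
    dplyr::arrange(dplyr::desc(.data$mean_score),
                   dplyr::desc(.data$mapped_genes), .data$pathway) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Score, test and rank pathways in one step
#'
#' Convenience wrapper joining [pathway_scores()] and
#' [pathway_enrichment()]; feed the result to [rank_pathways()].
#'
#' @inheritParams pathway_scores
#' @inheritParams pathway_enrichment
#' @return A tibble with the columns of both component results.
#' @export
pathway_analysis <- function(scores, top_genes, pathways,
                             universe = scores$symbol,
                             absent_as_zero = FALSE) {
  dplyr::left_join(
    pathway_scores(scores, pathways, absent_as_zero = absent_as_zero),
    pathway_enrichment(top_genes, pathways, universe),
    by = "pathway"
  )
}
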