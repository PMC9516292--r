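#' Read a mouse-to-human ortholog symbol table
#'
#' @param path Two-column tab-delimited file (`mouse_symbol`, `human_symbol`),
#'   with or without a header row.
#' @return A tibble with columns `mouse_symbol` and `human_symbol`. Duplicate
#'   mouse symbols keep their first mapping; empty symbols are rejected.
#' @export
read_ortholog_map <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("mouse_symbol", "human_symbol"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) > 0 && identical(tolower(unname(unlist(raw[1, ]))),
                                 c("mouse_symbol", "human_symbol"))) {
    raw <- raw[-1, ]
  }
  if (any(is.na(raw$mouse_symbol) | is.na(raw$human_symbol) |
            raw$mouse_symbol == "" | raw$human_symbol == "")) {
    abort(paste0("'", path, "' contains empty symbols"))
  }
  dplyr::distinct(raw, .data$mouse_symbol, .keep_all = TRUE)
}

#' Map a mouse DE gene set onto human gene symbols
#'
#' Translates each mouse symbol through the ortholog table so the set can be
#' scored against a human gene association network. Mouse symbols absent from
#' the table fall back to plain upper-casing when `fallback_uppercase` is on
#' (mouse/human symbols mostly differ only in case); with the fallback off,
#' unmapped genes are dropped and reported. When several mouse genes map to
#' the same human gene the human gene keeps the largest `node_weight` among
#' them, so the output can be smaller than the input but never invents a
#' weight.
#'
#' @param de_genes Tibble from [filter_de()] (columns `symbol`, `log2_ratio`,
#'   `node_weight`, `direction`), in mouse symbol space.
#' @param ortholog_map Tibble from [read_ortholog_map()].
#' @param fallback_uppercase Map table-missing symbols by upper-casing them
#'   (default `TRUE`).
#' @return A tibble with the same columns as `de_genes` but human `symbol`s,
#'   one row per distinct human gene.
#' @export
map_to_human <- function(de_genes, ortholog_map, fallback_uppercase = TRUE) {
  mapped <- dplyr::left_join(de_genes, ortholog_map,
                             by = c(symbol = "mouse_symbol"))
  unmapped <- is.na(mapped$human_symbol)
  if (any(unmapped)) {
    if (fallback_uppercase) {
      mapped$human_symbol[unmapped] <- toupper(mapped$symbol[unmapped])
    } else {
      inform(paste0(sum(unmapped), " mouse gene(s) without a human ortholog ",
                    "dropped: ",
                    paste(head(mapped$symbol[unmapped], 10), collapse = ", ")))
      mapped <- mapped[!unmapped, ]
    }
  }
  mapped |>
    dplyr::arrange(dplyr::desc(.data$node_weight), .data$symbol) |>
    dplyr::distinct(.data$human_symbol, .keep_all = TRUE) |>
    dplyr::transmute(
      symbol      = .data$human_symbol,
      log2_ratio  = .data$log2_ratio,
      node_weight = .data$node_weight,
      direction   = .data$direction
    )
}
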