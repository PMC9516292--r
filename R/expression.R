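#' Read a cuffdiff-style differential-expression table
#'
#' Parses the tab-delimited `gene_exp.diff` dialect produced by cuffdiff
#' (columns `test_id, gene_id, gene, locus, sample_1, sample_2, status,
#' value_1, value_2, log2(fold_change), test_stat, p_value, q_value,
#' significant`). Other dialects can be read by supplying `field_map`, a named
#' character vector translating the canonical names used here to the column
#' names present in the file.
#'
#' Rows whose FPKM or q-value fields are not numeric (cuffdiff writes `-` for
#' untested rows) are retained but their `status` is forced away from `"OK"`
#' so downstream filters ignore them. Row order is preserved.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param field_map Optional named character vector mapping canonical column
#'   names (`gene_id`, `gene_symbol`, `fpkm_a`, `fpkm_b`, `log2_ratio`,
#'   `p_value`, `q_value`, `status`, `significant`) to the file's column
#'   names. Unmentioned names fall back to the cuffdiff defaults.
#'
#' @return A tibble with one row per data row and columns `gene_id`,
#'   `gene_symbol`, `fpkm_a`, `fpkm_b`, `log2_ratio`, `p_value`, `q_value`,
#'   `status`, `significant`. `log2_ratio` is the log2 of condition-2 over
#'   condition-1 FPKM and may be `Inf`/`-Inf` when one FPKM is zero.
#'
#' @examples
#' tbl <- simulate_de_table(synth_config(seed = 1, n_genes = 50, n_up = 2,
#'                                       n_down = 3, n_null_psig = 5,
#'                                       n_untested = 2,
#'                                       n_shared_orthologs = 0))
#' path <- tempfile(fileext = ".diff")
#' write_diff(tbl$table, path)
#' read_diff(path)
#' @export
read_diff <- function(path, field_map = NULL) {
  defaults <- c(
    gene_id     = "gene_id",
    gene_symbol = "gene",
    fpkm_a      = "value_1",
    fpkm_b      = "value_2",
    log2_ratio  = "log2(fold_change)",
    p_value     = "p_value",
    q_value     = "q_value",
    status      = "status",
    significant = "significant"
  )
  if (!is.null(field_map)) {
    bad <- setdiff(names(field_map), names(defaults))
    if (length(bad) > 0) {
      abort(paste0("unknown canonical field(s) in `field_map`: ",
                   paste(bad, collapse = ", ")))
    }
    defaults[names(field_map)] <- field_map
  }

  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) == 0) {
    abort(paste0("'", path, "' has no header row: not a .diff table"))
  }
  missing <- setdiff(unname(defaults), names(raw))
  if (length(missing) > 0) {
    abort(paste0("required column(s) missing from '", path, "': ",
                 paste(missing, collapse = ", ")))
  }

  out <- tibble(
    gene_id     = raw[[defaults[["gene_id"]]]],
    gene_symbol = raw[[defaults[["gene_symbol"]]]],
    fpkm_a      = parse_diff_num(raw[[defaults[["fpkm_a"]]]]),
    fpkm_b      = parse_diff_num(raw[[defaults[["fpkm_b"]]]]),
    log2_ratio  = parse_diff_num(raw[[defaults[["log2_ratio"]]]]),
    p_value     = parse_diff_num(raw[[defaults[["p_value"]]]]),
    q_value     = parse_diff_num(raw[[defaults[["q_value"]]]]),
    status      = raw[[defaults[["status"]]]],
    significant = tolower(raw[[defaults[["significant"]]]]) %in%
      c("yes", "true", "1")
  )

  # rows cuffdiff marked OK but whose key numerics did not parse are demoted
  unparseable <- is.na(out$fpkm_a) | is.na(out$fpkm_b) | is.na(out$q_value)
  demote <- unparseable & out$status == "OK"
  if (any(demote)) out$status[demote] <- "FAIL"
  out
}

# cuffdiff numeric fields: "-" means untested, "inf"/"-inf" are genuine
parse_diff_num <- function(x) {
  x <- tolower(trimws(x))
  out <- suppressWarnings(as.numeric(x))
  out[x %in% c("inf", "+inf")] <- Inf
  out[x == "-inf"] <- -Inf
  out
}

#' Filter differentially expressed genes by fold change and q-value
#'
#' Keeps test-passing (`status == "OK"`) genes whose fold-change magnitude
#' `2^|log2_ratio|` is strictly greater than `fold_threshold` and whose
#' q-value is strictly below `q_threshold`, the selection the influence
#' analysis seeds from. Rows with a zero FPKM (infinite log2 ratio) are
#' excluded — their node weight would be unbounded — and reported via a
#' message. When a symbol appears in several passing rows only the row with
#' the largest `|log2_ratio|` is kept, so symbols are unique.
#'
#' @param records Tibble from [read_diff()] (or any tibble with the same
#'   columns).
#' @param fold_threshold Fold-change magnitude cut (strict), default 3.
#' @param q_threshold q-value cut (strict), default 0.05.
#'
#' @return A tibble of DE genes with columns `symbol`, `log2_ratio`,
#'   `node_weight` (`= |log2_ratio|`, the weight the gene carries into the
#'   network score) and `direction` (`"up"` or `"down"`). Attributes
#'   `fold_threshold` and `q_threshold` record the cuts used.
#' @export
filter_de <- function(records, fold_threshold = 3, q_threshold = 0.05) {
  stopifnot(fold_threshold > 0, q_threshold > 0)
  ok <- dplyr::filter(
    records,
    .data$status == "OK",
    !is.na(.data$fpkm_a), !is.na(.data$fpkm_b),
    .data$fpkm_a > 0 | .data$fpkm_b > 0,
    !is.na(.data$q_value), !is.na(.data$log2_ratio)
  )
  n_inf <- sum(!is.finite(ok$log2_ratio))
  if (n_inf > 0) {
    inform(paste0(n_inf, " gene(s) with a zero FPKM (infinite log2 ratio) ",
                  "excluded from the DE set"))
  }
  out <- ok |>
    dplyr::filter(
      is.finite(.data$log2_ratio),
      .data$fpkm_a > 0, .data$fpkm_b > 0,
      2^abs(.data$log2_ratio) > fold_threshold,
      .data$q_value < q_threshold
    ) |>
    dplyr::transmute(
      symbol      = .data$gene_symbol,
      log2_ratio  = .data$log2_ratio,
      node_weight = abs(.data$log2_ratio),
      direction   = ifelse(.data$log2_ratio > 0, "up", "down")
    ) |>
    dplyr::arrange(dplyr::desc(.data$node_weight)) |>
    dplyr::distinct(.data$symbol, .keep_all = TRUE)
  attr(out, "fold_threshold") <- fold_threshold
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Count genes significant at a p-value threshold
#'
#' Number of test-passing (`status == "OK"`) records with `p_value` strictly
#' below `p_threshold`; the headline "up- or downregulated" count before any
#' fold filtering.
#'
#' @inheritParams filter_de
#' @param p_threshold p-value cut (strict), default 0.05.
#' @return An integer count.
#' @export
count_significant <- function(records, p_threshold = 0.05) {
  sum(records$status == "OK" & !is.na(records$p_value) &
        records$p_value < p_threshold)
}

#' Relative quantification fold change by the 2^-ddCt method
#'
#' Computes `2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))`, the standard relative fold change
#' for qRT-PCR validation. Each reference argument may hold Ct values for
#' several internal-control genes (e.g. beta-actin and 18S rRNA); they are
#' combined by their arithmetic mean Ct.
#'
#' @param ct_target_treated,ct_target_control Ct of the target gene in the
#'   treated and control samples (single values).
#' @param ct_ref_treated,ct_ref_control Ct of the reference gene(s) in the
#'   treated and control samples (numeric vectors, averaged).
#' @return The fold change, a non-negative number (1 means no change).
#' @examples
#' ddct_fold(20, 15, 23, 15)  # 8: target 3 cycles earlier relative to ref
#' @export
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated,
            ct_target_control, ct_ref_control)
  if (!all(is.finite(vals))) {
    abort("all Ct values must be finite")
  }
  ddct <- (ct_target_treated - mean(ct_ref_treated)) -
    (ct_target_control - mean(ct_ref_control))
  2^(-ddct)
}
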