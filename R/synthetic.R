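#' Configuration for the synthetic-data generators
#'
#' One object fixes every knob of the generated study: a cuffdiff-style DE
#' table with planted up/down genes, a mouse-to-human ortholog table with a
#' controlled amount of many-to-one collapse, a modular weighted network
#' whose designated module carries the DE genes, pathway gene sets
#' overlapping the planted modules, and a promoter sequence with planted
#' motif sites and primer cassettes. Defaults mirror the study conditions:
#' 15 upregulated genes at 3- to 10-fold, 70 downregulated at 2.7- to
#' 10-fold, 739 genes significant at p < 0.05, and 85 mouse DE genes
#' collapsing to 75 distinct human genes.
#'
#' The single `seed` fans out to fixed per-generator substreams, so the DE
#' table, network, pathways and promoter can be regenerated independently
#' and adding one generator never perturbs another.
#'
#' @param seed Integer master seed.
#' @param n_genes Rows in the DE table.
#' @param n_up,n_down Planted up-/down-regulated gene counts.
#' @param up_fold_range,down_fold_range Fold-change magnitude intervals the
#'   planted effects are drawn from (uniformly).
#' @param n_null_psig Null genes given p < 0.05 but q >= 0.05, recreating the
#'   gap between nominal and FDR-controlled significance.
#' @param n_untested Rows emitted with `NOTEST` status and `-` fields.
#' @param n_shared_orthologs Mouse DE genes that map onto an already-used
#'   human symbol (many-to-one collapse).
#' @param n_modules,module_size Planted-partition network shape.
#' @param intra_p,inter_p Within-/between-module edge probabilities.
#' @param intra_weight_range,inter_weight_range Raw edge-weight intervals
#'   (arbitrary positive scale; [normalize_edge_weights()] maps them into
#'   \[0, 1\], within-module edges landing above the 0.2 subnetwork cutoff).
#' @param de_module Module index that hosts the human DE genes.
#' @param planted_overlap Fraction of each module included in its pathway.
#' @param n_decoy_pathways,decoy_size_range Random decoy pathways.
#' @param promoter_length Length of the generated promoter (default 1200,
#'   the 1.2 kb upstream region scanned in the study).
#' @param n_gre_sites Planted glucocorticoid-response-element sites.
#' @param gre_consensus IUPAC consensus instantiated at each planted site.
#' @param primer_cassettes List of cassettes, each
#'   `list(fwd_len=, spacer=, rev_len=)`; the planted amplicon length is
#'   `fwd_len + spacer + rev_len`.
#' @param influence_quantile Score quantile used as the influenced-gene cut
#'   on synthetic runs (the study's absolute 150 is specific to the
#'   full-scale linkage network). The default 0.75 keeps the influenced set
#'   about 2.7 times the seed count on the default network shape, the
#'   influenced-to-seed ratio of the full-scale analysis.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_genes = 5000, n_up = 15, n_down = 70,
                         up_fold_range = c(3, 10),
                         down_fold_range = c(2.7, 10),
                         n_null_psig = 654, n_untested = 50,
                         n_shared_orthologs = 10,
                         n_modules = 4, module_size = 100,
                         intra_p = 0.3, inter_p = 0.01,
                         intra_weight_range = c(3, 5),
                         inter_weight_range = c(0.1, 1.5),
                         de_module = 1,
                         planted_overlap = 0.8,
                         n_decoy_pathways = 20,
                         decoy_size_range = c(10, 50),
                         promoter_length = 1200,
                         n_gre_sites = 4,
                         gre_consensus = "GGTACANNNTGTTCT",
                         primer_cassettes = list(
                           list(fwd_len = 17, spacer = 95, rev_len = 22)
                         ),
                         influence_quantile = 0.75) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_up >= 0, cfg$n_down >= 0,
    cfg$n_up + cfg$n_down + cfg$n_untested <= cfg$n_genes,
    all(cfg$up_fold_range > 1), all(cfg$down_fold_range > 1),
    cfg$intra_p >= 0, cfg$intra_p <= 1, cfg$inter_p >= 0, cfg$inter_p <= 1,
    cfg$n_modules >= 1, cfg$module_size >= 1,
    cfg$n_shared_orthologs <= cfg$n_up + cfg$n_down,
    cfg$de_module >= 1, cfg$de_module <= cfg$n_modules
  )
  n_human_de <- cfg$n_up + cfg$n_down - cfg$n_shared_orthologs
  if (n_human_de > cfg$module_size) {
    abort("distinct human DE genes must fit inside the designated module")
  }
  if (cfg$n_null_psig >
        cfg$n_genes - cfg$n_up - cfg$n_down - cfg$n_untested) {
    abort("n_null_psig exceeds the number of null genes")
  }
  structure(cfg, class = "synth_config")
}

# deterministic symbol scheme shared by the generators: gene i is mouse
# "Gene%04d" / human toupper(); DE genes are indices 1..(n_up + n_down),
# the last n_shared_orthologs of which borrow the first human symbols
synth_symbols <- function(config) {
  n_de <- config$n_up + config$n_down
  mouse <- sprintf("Gene%04d", seq_len(config$n_genes))
  human <- toupper(mouse)
  if (config$n_shared_orthologs > 0) {
    shared <- seq(n_de - config$n_shared_orthologs + 1, n_de)
    human[shared] <- human[seq_len(config$n_shared_orthologs)]
  }
  list(
    mouse = mouse, human = human,
    up = mouse[seq_len(config$n_up)],
    down = mouse[config$n_up + seq_len(config$n_down)],
    de_mouse = mouse[seq_len(n_de)],
    de_human = unique(human[seq_len(n_de)])
  )
}

#' Generate a cuffdiff-style DE table with known ground truth
#'
#' Planted up/down genes draw fold-change magnitudes uniformly from the
#' configured ranges with q < 0.05; null genes sit near fold 1 (within
#' 2.5-fold, below any planted range) with q >= 0.05, a configured number of
#' them nominally significant (p < 0.05); a few rows are emitted untested
#' (`NOTEST`, `-` fields) as cuffdiff does. The emitted table round-trips
#' through [read_diff()].
#'
#' @param config A [synth_config()].
#' @return A list: `table` (tibble in `gene_exp.diff` column layout, ready
#'   for [write_diff()]) and `truth` (planted symbols, per-gene folds, and
#'   the p < 0.05 count among tested rows).
#' @export
simulate_de_table <- function(config) {
  set.seed(config$seed + 11L)
  sym <- synth_symbols(config)
  n_null <- config$n_genes - config$n_up - config$n_down - config$n_untested

  up_fold <- runif(config$n_up, config$up_fold_range[1],
                   config$up_fold_range[2])
  down_fold <- runif(config$n_down, config$down_fold_range[1],
                     config$down_fold_range[2])
  de_l2fc <- c(log2(up_fold), -log2(down_fold))
  de_q <- runif(length(de_l2fc), 5e-4, 0.049)
  de_p <- de_q * runif(length(de_l2fc), 0.05, 0.8)

  null_l2fc <- pmax(pmin(rnorm(n_null, 0, 0.25), 1.3), -1.3)
  null_p <- c(runif(config$n_null_psig, 1e-3, 0.0499),
              runif(n_null - config$n_null_psig, 0.05, 1))
  null_q <- pmin(1, pmax(null_p * runif(n_null, 1.5, 3), 0.05))

  n_tested <- config$n_genes - config$n_untested
  l2fc <- c(de_l2fc, null_l2fc)
  p <- c(de_p, null_p)
  q <- c(de_q, null_q)
  fpkm_a <- rlnorm(n_tested, meanlog = 3, sdlog = 1)
  fpkm_b <- fpkm_a * 2^l2fc

  tested <- tibble(
    test_id = sprintf("XLOC_%06d", seq_len(n_tested)),
    gene_id = sprintf("XLOC_%06d", seq_len(n_tested)),
    gene = sym$mouse[seq_len(n_tested)],
    locus = sprintf("chr%d:%d-%d", (seq_len(n_tested) %% 19) + 1,
                    1000 * seq_len(n_tested), 1000 * seq_len(n_tested) + 900),
    sample_1 = "WT", sample_2 = "cKO", status = "OK",
    value_1 = fpkm_a, value_2 = fpkm_b,
    `log2(fold_change)` = l2fc,
    test_stat = -sign(l2fc) * abs(qnorm(p / 2)),
    p_value = p, q_value = q,
    significant = q < 0.05
  )
  untested <- tibble(
    test_id = sprintf("XLOC_%06d", n_tested + seq_len(config$n_untested)),
    gene_id = sprintf("XLOC_%06d", n_tested + seq_len(config$n_untested)),
    gene = sym$mouse[n_tested + seq_len(config$n_untested)],
    locus = sprintf("chr1:%d-%d", seq_len(config$n_untested),
                    seq_len(config$n_untested) + 900),
    sample_1 = "WT", sample_2 = "cKO", status = "NOTEST",
    value_1 = NA_real_, value_2 = NA_real_,
    `log2(fold_change)` = NA_real_, test_stat = NA_real_,
    p_value = NA_real_, q_value = NA_real_, significant = FALSE
  )
  table <- dplyr::bind_rows(tested, untested)
  table <- table[sample.int(nrow(table)), ]

  truth <- list(
    up = sym$up, down = sym$down, de = sym$de_mouse,
    de_human = sym$de_human,
    folds = tibble(symbol = sym$de_mouse,
                   log2_ratio = de_l2fc,
                   fold = c(up_fold, down_fold)),
    n_p_significant = sum(table$status == "OK" &
                            table$p_value < 0.05, na.rm = TRUE),
    min_planted_fold = if (length(c(up_fold, down_fold)) == 0) NA_real_ else
      min(up_fold, down_fold)
  )
  list(table = table, truth = truth)
}

#' Write a DE table in cuffdiff `.diff` layout
#'
#' Tab-delimited with the `gene_exp.diff` header; `NA` numeric fields are
#' written as `-` and logical `significant` as `yes`/`no`, as cuffdiff does.
#'
#' @param table Tibble in the layout produced by [simulate_de_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diff <- function(table, path) {
  out <- table
  num_cols <- c("value_1", "value_2", "log2(fold_change)", "test_stat",
                "p_value", "q_value")
  for (cc in num_cols) {
    v <- as.character(out[[cc]])
    v[is.na(v)] <- "-"
    out[[cc]] <- v
  }
  out$significant <- ifelse(out$significant, "yes", "no")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Generate the mouse-to-human ortholog table
#'
#' Deterministic given the configuration (no randomness): every mouse symbol
#' maps to its upper-cased human form except the configured shared-ortholog
#' genes, which map onto already-used human symbols to exercise many-to-one
#' collapse.
#'
#' @inheritParams simulate_de_table
#' @return A tibble (`mouse_symbol`, `human_symbol`).
#' @export
simulate_ortholog_map <- function(config) {
  sym <- synth_symbols(config)
  tibble(mouse_symbol = sym$mouse, human_symbol = sym$human)
}

#' Write an ortholog table to TSV
#'
#' @param map Tibble (`mouse_symbol`, `human_symbol`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Generate a modular weighted network with planted ground truth
#'
#' Planted-partition graph: dense, heavy edges within modules and sparse,
#' light edges between them, on an arbitrary positive raw-weight scale (use
#' [normalize_edge_weights()] before scoring). The distinct human DE symbols
#' are placed (shuffled) inside the designated module; remaining nodes are
#' background genes.
#'
#' @inheritParams simulate_de_table
#' @return A list: `network` (raw-weight edge tibble) and `truth`
#'   (`membership` tibble `symbol`/`module`, and `de_module`).
#' @export
simulate_network <- function(config) {
  set.seed(config$seed + 23L)
  sym <- synth_symbols(config)
  n_nodes <- config$n_modules * config$module_size
  de_human <- sym$de_human
  n_bg <- n_nodes - length(de_human)
  bg <- sprintf("BG%05d", seq_len(n_bg))

  membership <- rep(seq_len(config$n_modules), each = config$module_size)
  nodes <- character(n_nodes)
  de_slots <- which(membership == config$de_module)
  de_slots <- sample(de_slots, length(de_human))
  nodes[de_slots] <- de_human
  nodes[nodes == ""] <- bg

  pairs <- utils::combn(n_nodes, 2)
  same <- membership[pairs[1, ]] == membership[pairs[2, ]]
  p_edge <- ifelse(same, config$intra_p, config$inter_p)
  keep <- runif(ncol(pairs)) < p_edge
  a <- pairs[1, keep]; b <- pairs[2, keep]; same <- same[keep]
  w <- ifelse(same,
              runif(sum(keep), config$intra_weight_range[1],
                    config$intra_weight_range[2]),
              runif(sum(keep), config$inter_weight_range[1],
                    config$inter_weight_range[2]))
  network <- canonicalize_edges(
    tibble(gene_a = nodes[a], gene_b = nodes[b], weight = w)
  )
  list(
    network = network,
    truth = list(
      membership = tibble(symbol = nodes, module = membership),
      de_module = config$de_module
    )
  )
}

#' Generate pathway gene sets overlapping the planted modules
#'
#' One pathway per module containing a configured fraction of that module's
#' genes, plus random decoy pathways drawn from the whole network universe.
#'
#' @inheritParams simulate_de_table
#' @param membership Optional module-membership tibble (from
#'   [simulate_network()] truth); regenerated from `config` when omitted.
#' @return A list: `pathways` (long tibble `pathway`/`symbol`) and `truth`
#'   (the pathway planted on the DE module, and per-pathway module of
#'   origin).
#' @export
simulate_pathways <- function(config, membership = NULL) {
  if (is.null(membership)) {
    membership <- simulate_network(config)$truth$membership
  }
  set.seed(config$seed + 37L)
  module_sets <- split(membership$symbol, membership$module)
  planted <- purrr::imap(module_sets, function(genes, m) {
    tibble(pathway = sprintf("PW_M%s", m),
           symbol = sort(sample(genes,
                                ceiling(config$planted_overlap *
                                          length(genes)))))
  })
  decoys <- purrr::map(seq_len(config$n_decoy_pathways), function(d) {
    size <- sample(seq(config$decoy_size_range[1],
                       config$decoy_size_range[2]), 1)
    tibble(pathway = sprintf("PW_D%02d", d),
           symbol = sort(sample(membership$symbol, size)))
  })
  pathways <- dplyr::bind_rows(c(unname(planted), unname(decoys)))
  list(
    pathways = pathways,
    truth = list(
      de_pathway = sprintf("PW_M%d", config$de_module),
      module_of = setNames(names(module_sets),
                           sprintf("PW_M%s", names(module_sets)))
    )
  )
}

#' Generate a promoter sequence with planted motif sites and primer cassettes
#'
#' Random background sequence with (1) the configured number of motif
#' consensus instances (ambiguity codes instantiated randomly) and (2) primer
#' cassettes `forward + spacer + reverse-complement(reverse)` planted at
#' recorded, non-overlapping positions. Planted features are laid out in
#' evenly sized slots at random offsets; a configuration whose features
#' cannot fit raises an error.
#'
#' @inheritParams simulate_de_table
#' @return A list: `seqs` (a one-sequence [Biostrings::DNAStringSet] named
#'   `promoter`), and `truth` (feature coordinates, the primer pairs with
#'   their expected amplicon lengths).
#' @export
simulate_promoter <- function(config) {
  set.seed(config$seed + 41L)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")

  gre_len <- nchar(config$gre_consensus)
  cassettes <- purrr::map(config$primer_cassettes, function(cs) {
    fwd <- rand_seq(cs$fwd_len)
    rev <- rand_seq(cs$rev_len)
    rc_rev <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(rev)))
    list(forward = fwd, reverse = rev,
         insert = paste0(fwd, rand_seq(cs$spacer), rc_rev),
         amplicon_length = cs$fwd_len + cs$spacer + cs$rev_len)
  })
  instantiate <- function(consensus) {
    codes <- strsplit(toupper(consensus), "")[[1]]
    paste(vapply(codes, function(cc) {
      opts <- IUPAC_BASES[[cc]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }
  features <- c(
    purrr::map(seq_len(config$n_gre_sites), function(i) {
      list(type = "gre", insert = instantiate(config$gre_consensus))
    }),
    purrr::map(cassettes, function(cs) {
      list(type = "cassette", insert = cs$insert)
    })
  )

  n_feat <- length(features)
  if (n_feat == 0) {
    seq <- rand_seq(config$promoter_length)
    return(list(seqs = Biostrings::DNAStringSet(c(promoter = seq)),
                truth = list(features = tibble(type = character(),
                                               start = integer(),
                                               end = integer()),
                             cassettes = list())))
  }
  slot <- config$promoter_length %/% n_feat
  feat_lens <- vapply(features, function(f) nchar(f$insert), integer(1))
  if (any(feat_lens > slot)) {
    abort("planted features do not fit in the promoter without overlap")
  }
  starts <- vapply(seq_len(n_feat), function(i) {
    as.integer((i - 1L) * slot + sample.int(slot - feat_lens[i] + 1L, 1))
  }, integer(1))

  seq_chars <- strsplit(rand_seq(config$promoter_length), "")[[1]]
  for (i in seq_len(n_feat)) {
    ins <- strsplit(features[[i]]$insert, "")[[1]]
    seq_chars[starts[i]:(starts[i] + feat_lens[i] - 1)] <- ins
  }
  seq <- paste(seq_chars, collapse = "")

  truth <- list(
    features = tibble(
      type = vapply(features, `[[`, "", "type"),
      start = starts,
      end = starts + feat_lens - 1L
    ),
    cassettes = purrr::map(cassettes, function(cs) {
      cs[c("forward", "reverse", "amplicon_length")]
    })
  )
  list(seqs = Biostrings::DNAStringSet(c(promoter = seq)), truth = truth)
}

#' Generate every pipeline input into a directory
#'
#' Emits `genes.diff`, `network.tsv`, `orthologs.tsv`, `pathways.gmt`,
#' `promoter.fa` and `truth.json`; each file parses with the package's
#' corresponding reader, and identical configurations produce byte-identical
#' files.
#'
#' @inheritParams simulate_de_table
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths` and the combined `truth`.
#' @export
generate_synthetic_data <- function(out_dir, config = synth_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  de <- simulate_de_table(config)
  net <- simulate_network(config)
  pw <- simulate_pathways(config, membership = net$truth$membership)
  prom <- simulate_promoter(config)
  orth <- simulate_ortholog_map(config)

  paths <- list(
    diff = file.path(out_dir, "genes.diff"),
    network = file.path(out_dir, "network.tsv"),
    orthologs = file.path(out_dir, "orthologs.tsv"),
    gmt = file.path(out_dir, "pathways.gmt"),
    fasta = file.path(out_dir, "promoter.fa"),
    truth = file.path(out_dir, "truth.json")
  )
  write_diff(de$table, paths$diff)
  write_network(net$network, paths$network)
  write_ortholog_map(orth, paths$orthologs)
  write_gmt(pw$pathways, paths$gmt)
  write_fasta(prom$seqs, paths$fasta)

  truth <- list(
    de = de$truth[c("up", "down", "de", "de_human", "n_p_significant",
                    "min_planted_fold")],
    network = list(de_module = net$truth$de_module,
                   membership = as.list(setNames(
                     net$truth$membership$module,
                     net$truth$membership$symbol))),
    pathways = pw$truth["de_pathway"],
    promoter = list(
      features = as.list(prom$truth$features),
      cassettes = prom$truth$cassettes
    )
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth))
}
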