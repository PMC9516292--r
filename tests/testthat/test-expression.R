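test_that("read_diff round-trips the synthetic writer and flags bad rows", {
  cfg <- synth_config(seed = 3, n_genes = 60, n_up = 3, n_down = 4,
                      n_null_psig = 10, n_untested = 5,
                      n_shared_orthologs = 0)
  gen <- simulate_de_table(cfg)
  path <- tempfile(fileext = ".diff")
  write_diff(gen$table, path)
  rec <- read_diff(path)

  expect_equal(nrow(rec), 60)
  expect_identical(rec$gene_symbol, gen$table$gene)          # order preserved
  ok <- gen$table$status == "OK"
  expect_equal(rec$fpkm_a[ok], gen$table$value_1[ok])
  expect_equal(rec$fpkm_b[ok], gen$table$value_2[ok])
  expect_equal(rec$log2_ratio[ok], gen$table$`log2(fold_change)`[ok])
  expect_equal(rec$q_value[ok], gen$table$q_value[ok])
  # untested rows ("-" fields) keep a non-OK status and NA numerics
  expect_true(all(rec$status[!ok] != "OK"))
  expect_true(all(is.na(rec$q_value[!ok])))
})

test_that("read_diff handles header-only files, missing columns, mappings", {
  hdr <- paste(c("test_id", "gene_id", "gene", "locus", "sample_1",
                 "sample_2", "status", "value_1", "value_2",
                 "log2(fold_change)", "test_stat", "p_value", "q_value",
                 "significant"), collapse = "\t")
  expect_equal(nrow(read_diff(write_lines_tmp(hdr))), 0)

  bad <- write_lines_tmp(sub("\tq_value", "\tqval", hdr))
  expect_error(read_diff(bad), "q_value")
  expect_equal(nrow(read_diff(write_lines_tmp(sub("\tq_value", "\tqval", hdr)),
                              field_map = c(q_value = "qval"))), 0)
  expect_error(read_diff(write_lines_tmp(character())), "header")

  # a row cuffdiff calls OK but with unparseable FPKM is demoted
  row <- paste(c("x", "x", "GeneX", "chr1:1-2", "WT", "cKO", "OK", "-",
                 "5", "1.2", "0", "0.01", "0.02", "yes"), collapse = "\t")
  rec <- read_diff(write_lines_tmp(c(hdr, row)))
  expect_false(rec$status == "OK")

  # infinite log2 ratios parse as such
  row2 <- paste(c("y", "y", "GeneY", "chr1:1-2", "WT", "cKO", "OK", "0",
                  "5", "inf", "0", "0.01", "0.02", "yes"), collapse = "\t")
  expect_identical(read_diff(write_lines_tmp(c(hdr, row2)))$log2_ratio, Inf)
})

make_records <- function(l2fc, q, p = q / 2, status = "OK",
                         symbol = sprintf("G%02d", seq_along(l2fc))) {
  tibble::tibble(
    gene_id = symbol, gene_symbol = symbol,
    fpkm_a = 10, fpkm_b = 10 * 2^l2fc, log2_ratio = l2fc,
    p_value = p, q_value = q, status = status, significant = q < 0.05
  )
}

test_that("filter_de applies both cuts strictly and keeps |log2| weights", {
  rec <- make_records(
    l2fc = c(0, log2(2.5), 2, -log2(10.4), log2(4)),
    q    = c(0.001, 0.01, 0.01, 0.049, 0.06)
  )
  de <- filter_de(rec)
  # fold 1 and fold 2.5 fail the fold cut; fold 4 with q=0.06 fails q cut
  expect_setequal(de$symbol, c("G03", "G04"))
  expect_equal(de$node_weight[de$symbol == "G03"], 2)
  g4 <- de[de$symbol == "G04", ]
  expect_equal(g4$node_weight, log2(10.4), tolerance = 1e-6)
  expect_equal(g4$node_weight, 3.3785, tolerance = 1e-4)
  expect_identical(g4$direction, "down")

  # boundary: fold exactly 3 and q exactly 0.05 are both excluded
  bound <- make_records(l2fc = c(log2(3), 1.9), q = c(0.01, 0.05))
  expect_equal(nrow(filter_de(bound)), 0)
})

test_that("filter_de drops non-OK and infinite-ratio rows, dedups symbols", {
  rec <- dplyr::bind_rows(
    make_records(3, 0.01, status = "NOTEST", symbol = "A"),
    make_records(c(2, 3), c(0.01, 0.01), symbol = c("B", "B")),
    tibble::tibble(gene_id = "C", gene_symbol = "C", fpkm_a = 0, fpkm_b = 5,
                   log2_ratio = Inf, p_value = 0.001, q_value = 0.001,
                   status = "OK", significant = TRUE)
  )
  expect_message(de <- filter_de(rec), "infinite")
  expect_identical(de$symbol, "B")
  expect_equal(de$node_weight, 3)  # the larger of the duplicate rows
})

test_that("filter_de is monotone in both thresholds", {
  set.seed(42)
  rec <- make_records(l2fc = runif(200, -5, 5), q = runif(200))
  for (i in 1:10) {
    f1 <- sort(runif(2, 1.5, 6)); q1 <- sort(runif(2, 0.001, 0.2))
    loose <- filter_de(rec, fold_threshold = f1[1], q_threshold = q1[2])
    tight <- filter_de(rec, fold_threshold = f1[2], q_threshold = q1[1])
    expect_true(all(tight$symbol %in% loose$symbol))
  }
})

test_that("count_significant counts OK records below the p cut", {
  expect_equal(count_significant(make_records(numeric(0), numeric(0))), 0)
  rec <- make_records(l2fc = rep(1, 10), q = rep(0.5, 10),
                      p = c(rep(0.01, 4), rep(0.5, 6)))
  expect_equal(count_significant(rec), 4)
  rec$status[1] <- "FAIL"
  expect_equal(count_significant(rec), 3)
  expect_equal(count_significant(rec, p_threshold = 0.6), 9)
})

test_that("ddct_fold implements 2^-ddCt with mean-combined references", {
  expect_equal(ddct_fold(20, 20, 20, 20), 1)
  for (x in c(15, 22.3)) for (y in c(18, 30)) {
    expect_equal(ddct_fold(x, x, y, y), 1)
  }
  expect_equal(ddct_fold(21, 20, 20, 20), 0.5)   # ddCt = +1
  expect_equal(ddct_fold(19, 20, 20, 20), 4 / 2) # ddCt = -1 -> 2
  expect_equal(ddct_fold(20, 15, 23, 15), 8)
  # two internal controls enter via their arithmetic mean Ct
  expect_equal(ddct_fold(20, c(14, 16), 23, c(15, 15)), 8)
  expect_error(ddct_fold(20, NA, 23, 15), "finite")
  expect_error(ddct_fold(Inf, 15, 23, 15), "finite")
})
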