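IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to a FASTA file
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_dna_set(seqs), path)
  invisible(path)
}

as_dna_set <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) return(seqs)
  if (methods::is(seqs, "DNAString")) seqs <- as.character(seqs)
  if (is.character(seqs)) {
    if (is.null(names(seqs))) {
      names(seqs) <- if (length(seqs) == 1) "seq1" else
        paste0("seq", seq_along(seqs))
    }
    return(Biostrings::DNAStringSet(seqs))
  }
  abort("`seqs` must be a DNAStringSet or a (named) character vector")
}

# base -> row index in A/C/G/T space; ambiguity codes (incl. N) give NA so
# they never count as a match and contribute 0 to a PWM score
base_index <- function(seq_chr) {
  match(strsplit(toupper(seq_chr), "")[[1]], c("A", "C", "G", "T"))
}

# 4 x L logical matrix: which of A/C/G/T each consensus position admits
consensus_matrix_logical <- function(consensus) {
  codes <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(codes, names(IUPAC_BASES))
  if (length(bad) > 0) {
    abort(paste0("invalid IUPAC code(s) in consensus: ",
                 paste(unique(bad), collapse = ", ")))
  }
  vapply(codes, function(cc) c("A", "C", "G", "T") %in% IUPAC_BASES[[cc]],
         logical(4))
}

validate_pwm <- function(pwm) {
  if (!is.matrix(pwm) || nrow(pwm) != 4) {
    abort("a PWM motif must be a 4-row matrix (A, C, G, T) with one column per position")
  }
  if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(pwm) - 1) > 1e-6)) {
    abort("PWM position probabilities must each sum to 1")
  }
  pwm
}

# windowed motif score along one strand; returns fraction-of-maximum
window_scores <- function(base_idx, score_mat, max_score) {
  L <- ncol(score_mat)
  n_win <- length(base_idx) - L + 1
  s <- numeric(n_win)
  for (p in seq_len(L)) {
    contrib <- score_mat[cbind(base_idx[p:(p + n_win - 1)], p)]
    contrib[is.na(contrib)] <- 0
    s <- s + contrib
  }
  s / max_score
}

#' Scan sequences for a motif given as IUPAC consensus or PWM
#'
#' Slides the motif along each sequence (and its reverse complement when
#' `both_strands` is on) and reports every window whose score reaches
#' `threshold` times the maximum attainable score. For a consensus motif the
#' window score is the fraction of positions whose base is admitted by the
#' IUPAC code at that position; for a PWM (4 rows A/C/G/T of per-position
#' probabilities) it is the summed probability of the window's bases.
#' Ambiguous bases in the *sequence* (e.g. N) never match and score 0.
#' Minus-strand hits are reported in forward-strand coordinates with
#' `strand = "-"`. The default motif is the classical glucocorticoid
#' response element half-site consensus `GGTACANNNTGTTCT`.
#'
#' @param seqs A [Biostrings::DNAStringSet], named character vector, or a
#'   single sequence string.
#' @param motif IUPAC consensus string, or a 4-row probability matrix.
#' @param threshold Fraction of the maximum score required for a hit, in
#'   \[0, 1\] (default 0.85).
#' @param both_strands Also scan the reverse complement (default `TRUE`).
#' @return A tibble of hits: `seq_id`, `start`, `end` (1-based inclusive),
#'   `strand`, `score` (fraction of maximum). Sequences shorter than the
#'   motif produce no hits, with a warning.
#' @examples
#' scan_motif(c(pro = "AAGGTACAGTTTGTTCTAA"), "GGTACANNNTGTTCT")
#' @export
scan_motif <- function(seqs, motif = "GGTACANNNTGTTCT", threshold = 0.85,
                       both_strands = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  seqs <- as_dna_set(seqs)
  if (is.character(motif)) {
    score_mat <- consensus_matrix_logical(motif) * 1
    max_score <- ncol(score_mat)
  } else {
    score_mat <- validate_pwm(motif)
    max_score <- sum(apply(score_mat, 2, max))
  }
  L <- ncol(score_mat)

  one_strand <- function(seq_chr) {
    s <- window_scores(base_index(seq_chr), score_mat, max_score)
    hit <- which(s >= threshold - 1e-12)
    tibble(start = hit, score = s[hit])
  }

  out <- purrr::map(seq_along(seqs), function(i) {
    seq_chr <- as.character(seqs[[i]])
    n <- nchar(seq_chr)
    if (n < L) {
      warn(paste0("sequence '", names(seqs)[i], "' (", n,
                  " nt) is shorter than the motif (", L, " nt)"))
      return(NULL)
    }
    plus <- one_strand(seq_chr) |>
      dplyr::mutate(strand = "+")
    res <- plus
    if (both_strands) {
      rc <- as.character(Biostrings::reverseComplement(seqs[[i]]))
      minus <- one_strand(rc) |>
        dplyr::mutate(start = n - .data$start - L + 2, strand = "-")
      res <- dplyr::bind_rows(plus, minus)
    }
    dplyr::mutate(res, seq_id = names(seqs)[i],
                  end = .data$start + L - 1)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), score = double()))
  }
  res |>
    dplyr::select("seq_id", "start", "end", "strand", "score") |>
    dplyr::arrange(.data$seq_id, .data$start, .data$strand)
}

match_starts <- function(pattern, subject, max_mismatch = 0,
                         protect_3prime_left = FALSE) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                   max.mismatch = max_mismatch)
  starts <- Biostrings::start(hits)
  if (max_mismatch > 0 && length(starts) > 0) {
    mm <- Biostrings::mismatch(Biostrings::DNAString(pattern), hits)
    L <- nchar(pattern)
    keep <- vapply(mm, function(pos) {
      # disallow mismatches in the primer's 3' 5-mer; for a left-oriented
      # (reverse-complemented) pattern the primer's 3' end is position 1..5
      if (protect_3prime_left) all(pos > 5) else all(pos <= L - 5)
    }, logical(1))
    starts <- starts[keep]
  }
  starts
}

#' Exact-match in-silico PCR
#'
#' Predicts PCR products for a primer pair against template sequences. The
#' forward primer is matched on the plus strand and the reverse complement of
#' the reverse primer downstream of it; the symmetric opposite orientation
#' (product on the minus strand) is also scanned. Matching is exact by
#' default; with `max_mismatch > 0`, up to that many mismatches are allowed
#' per primer but never within the 3' 5-mer, where extension requires a
#' perfect duplex. Product length spans both primers inclusively
#' (`end - start + 1`). All non-overlapping primer-site pairings within
#' `max_product` are reported.
#'
#' @param seqs A [Biostrings::DNAStringSet], named character vector, or a
#'   single sequence string.
#' @param forward,reverse Primer sequences, each written 5'->3' on its own
#'   strand (the usual primer-table convention), A/C/G/T only, length >= 10.
#' @param max_product Longest product reported, default 5000 bp.
#' @param max_mismatch Mismatches tolerated per primer outside its 3' 5-mer
#'   (default 0 = exact).
#' @return A tibble of amplicons: `seq_id`, `start`, `end` (1-based
#'   inclusive on the plus strand), `length`, `orientation` (`"+"` product
#'   read left-to-right from the forward primer, `"-"` the converse).
#' @examples
#' tmpl <- paste0("GGACAACCTGACTTCCTTGG", strsplit("ACGT", "")[[1]][1],
#'                "GTGAGTTCTCCTCCGTCCAG")
#' in_silico_pcr(c(amp = tmpl), "GGACAACCTGACTTCCTTGG", "CTGGACGGAGGAGAACTCAC")
#' @export
in_silico_pcr <- function(seqs, forward, reverse, max_product = 5000,
                          max_mismatch = 0) {
  check_primer <- function(p, what) {
    p <- toupper(p)
    if (nchar(p) < 10 || grepl("[^ACGT]", p)) {
      abort(paste0(what, " primer must be >= 10 nt of A/C/G/T"))
    }
    p
  }
  forward <- check_primer(forward, "forward")
  reverse <- check_primer(reverse, "reverse")
  seqs <- as_dna_set(seqs)
  rc <- function(p) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(p)))

  pair_up <- function(left_starts, left_len, right_starts, right_len) {
    grid <- expand.grid(ls = left_starts, rs = right_starts)
    grid <- grid[grid$rs > grid$ls + left_len - 1, , drop = FALSE]
    tibble(start = grid$ls, end = grid$rs + right_len - 1) |>
      dplyr::mutate(length = .data$end - .data$start + 1) |>
      dplyr::filter(.data$length <= max_product)
  }

  out <- purrr::map(seq_along(seqs), function(i) {
    subject <- seqs[[i]]
    fwd_plus <- pair_up(
      match_starts(forward, subject, max_mismatch),
      nchar(forward),
      match_starts(rc(reverse), subject, max_mismatch,
                   protect_3prime_left = TRUE),
      nchar(reverse)
    ) |> dplyr::mutate(orientation = "+")
    fwd_minus <- pair_up(
      match_starts(reverse, subject, max_mismatch),
      nchar(reverse),
      match_starts(rc(forward), subject, max_mismatch,
                   protect_3prime_left = TRUE),
      nchar(forward)
    ) |> dplyr::mutate(orientation = "-")
    dplyr::bind_rows(fwd_plus, fwd_minus) |>
      dplyr::mutate(seq_id = names(seqs)[i])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  length = integer(), orientation = character()))
  }
  res |>
    dplyr::select("seq_id", "start", "end", "length", "orientation") |>
    dplyr::arrange(.data$seq_id, .data$start, .data$end)
}
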