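#' Per-column score dispersion
#'
#' The population standard deviation of the 16 dinucleotide scores of each
#' column. A large value marks a selective position pair (a few dinucleotides
#' dominate); near-zero marks a nonselective one where almost every word gets
#' a similar score, which is what inflates valid-word sets.
#'
#' @param x A [dipwm].
#' @return Numeric vector of length `m - 1`.
#' @export
column_score_sd <- function(x) {
  stopifnot(inherits(x, "dipwm"))
  mu <- colMeans(x$scores)
  sqrt(colMeans(x$scores^2) - mu^2)
}

#' Select the high-selectivity core of a di-PWM
#'
#' Scans all column intervals of length at least `min_cols` exhaustively and
#' keeps the one with the largest average per-column score standard
#' deviation; ties go to the shorter, then the leftmost, interval. When the
#' matrix has at most `min_cols` columns the whole matrix is the core.
#' Restricting enumeration to the core keeps word sets small for matrices
#' with runs of nonselective positions.
#'
#' @param x A [dipwm].
#' @param min_cols Minimum number of columns in the core interval
#'   (default 10, i.e. core words of at least 11 nucleotides).
#' @return A `dipwm_core` object with fields `a`, `b` (first/last column,
#'   1-based), `k = a - 1` (offset of the core in the motif), `h = b - a + 2`
#'   (core word length in nucleotides) and `avg_stddev`.
#' @export
select_core <- function(x, min_cols = 10) {
  stopifnot(inherits(x, "dipwm"))
  if (!is.numeric(min_cols) || min_cols < 1) {
    abort("min_cols must be a positive integer", class = "dipwmscan_input_error")
  }
  min_cols <- as.integer(min_cols)
  nc <- x$m - 1L
  sds <- column_score_sd(x)
  if (nc <= min_cols) {
    return(new_core(1L, nc, mean(sds)))
  }
  cum <- c(0, cumsum(sds))
  best <- NULL
  for (len in seq(min_cols, nc)) {        # shorter lengths first: tie-break
    for (a in seq_len(nc - len + 1L)) {
      avg <- (cum[a + len] - cum[a]) / len
      if (is.null(best) || avg > best$avg_stddev) {
        best <- new_core(a, a + len - 1L, avg)
      }
    }
  }
  best
}

new_core <- function(a, b, avg) {
  structure(
    list(a = as.integer(a), b = as.integer(b), k = as.integer(a) - 1L,
         h = as.integer(b) - as.integer(a) + 2L, avg_stddev = avg),
    class = "dipwm_core"
  )
}

#' @export
print.dipwm_core <- function(x, ...) {
  cat(sprintf(
    "di-PWM core: columns %d..%d (offset k = %d, core word length h = %d), mean column sd %.4g\n",
    x$a, x$b, x$k, x$h, x$avg_stddev))
  invisible(x)
}

# Shared driver for both enumerators.
enumerate_block <- function(x, a, b, t, cap) {
  lam <- dipwm_lam(x)
  lbm <- dipwm_lbm(x)
  res <- cpp_enumerate(x$scores, lam, lbm, a, b, t - SCORE_TOL, cap)
  if (isTRUE(res$truncated)) {
    abort(sprintf(
      "more than %g valid words; raise the threshold or use the window scanner (os)",
      cap), class = "dipwmscan_resource_error")
  }
  res
}

#' Enumerate all valid words of a di-PWM
#'
#' Walks the trie of ACGT words depth-first, pruning every prefix whose
#' partial score plus the best realizable suffix score (from the LookAhead
#' matrix) falls below the threshold. Because every LookAhead entry is
#' attained by a concrete word, only branches leading to valid words are
#' explored, and the work between two emitted words stays bounded by about
#' twice the motif length, making the enumeration linear in its output size.
#' Words come out in lexicographic order. Comparison with the threshold is
#' `>=` (within a 1e-9 absolute tolerance shared by all score comparisons),
#' so a ratio-1 threshold yields the maximal-score word(s).
#'
#' @param x A [dipwm].
#' @param threshold A threshold spec or absolute score (see
#'   [threshold_score()]); P-value mode needs `dist`.
#' @param dist Optional [score_distribution()], used for P-value thresholds.
#' @param cap Abort (with a resource error) if more than this many words
#'   qualify; guards against nonselective matrices at permissive thresholds.
#' @return A tibble with columns `word` and `score` (the exact word score),
#'   in lexicographic word order, with attributes `word_index` (the base-4
#'   rank of each word among all 4^m words, as a double), `nodes_visited`
#'   (trie nodes expanded) and `threshold` (the resolved score).
#' @export
enumerate_words <- function(x, threshold, dist = NULL, cap = 5e6) {
  stopifnot(inherits(x, "dipwm"))
  t <- resolve_threshold(x, threshold, dist)
  res <- enumerate_block(x, 1L, x$m - 1L, t, cap)
  out <- tibble(word = res$word, score = res$score)
  attr(out, "word_index") <- res$index
  attr(out, "nodes_visited") <- res$nodes
  attr(out, "threshold") <- t
  out
}

#' Enumerate core words
#'
#' Enumerates words of length `h = b - a + 2` over the core columns
#' `a..b`, keeping a core word `w` when its best full-length extension can
#' reach the threshold: `LBM[w1, a] + score(w over a..b) + LAM[wh, b + 1]`,
#' i.e. the best prefix ending with `w`'s first letter plus the best suffix
#' starting with its last letter, both realizable. Every full-length valid
#' word therefore has its core substring in the output (no false negatives);
#' candidate matches found through this set are rescored against the full
#' matrix by the search phase.
#'
#' @inheritParams enumerate_words
#' @param core A [select_core()] interval (defaults to the selected core).
#' @return A tibble with columns `word` (length `h`) and `best_score` (the
#'   extension bound), lexicographic order, with the same attributes as
#'   [enumerate_words()].
#' @export
enumerate_core_words <- function(x, threshold, core = select_core(x),
                                 dist = NULL, cap = 5e6) {
  stopifnot(inherits(x, "dipwm"), inherits(core, "dipwm_core"))
  if (core$a < 1 || core$b > x$m - 1L || core$a > core$b) {
    abort("core interval lies outside the matrix", class = "dipwmscan_input_error")
  }
  t <- resolve_threshold(x, threshold, dist)
  res <- enumerate_block(x, core$a, core$b, t, cap)
  out <- tibble(word = res$word, best_score = res$score)
  attr(out, "word_index") <- res$index
  attr(out, "nodes_visited") <- res$nodes
  attr(out, "threshold") <- t
  out
}

#' Read and write plain-text word lists
#'
#' One word per line, with an optional tab-separated score column; the format
#' lets an enumerated valid-word set be stored and reused across searches.
#'
#' @param words A tibble as returned by [enumerate_words()] or
#'   [enumerate_core_words()] (any tibble whose first column is `word` and
#'   whose optional second column is numeric).
#' @param file Path.
#' @return `read_words()`: a tibble with column `word` and, when present in
#'   the file, `score`.
#' @export
write_words <- function(words, file) {
  stopifnot(is.data.frame(words), "word" %in% names(words))
  scorecol <- setdiff(names(words), "word")
  if (length(scorecol) >= 1) {
    writeLines(paste(words$word,
                     formatC(words[[scorecol[1]]], digits = 10, format = "g"),
                     sep = "\t"), file)
  } else {
    writeLines(words$word, file)
  }
  invisible(file)
}

#' @rdname write_words
#' @export
read_words <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(tibble(word = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1L)
  if (all(lengths(parts) >= 2)) {
    tibble(word = words,
           score = as.numeric(vapply(parts, `[[`, character(1), 2L)))
  } else {
    tibble(word = words)
  }
}
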