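#' Construct a dinucleotide position weight matrix
#'
#' A di-PWM scores a DNA word of length `m` by summing, over the `m - 1`
#' pairs of adjacent positions, the weight of the dinucleotide observed at
#' that pair. Column `i` therefore holds 16 weights, one per dinucleotide
#' `AA, AC, ..., TT` (lexicographic order over the fixed alphabet A, C, G, T),
#' and captures the dependency between motif positions `i` and `i + 1` that an
#' ordinary mononucleotide PWM ignores. Weights are arbitrary finite reals
#' (typically log-odds-style scores, but no distributional assumption is
#' made).
#'
#' @param scores A 16-row numeric matrix (rows = dinucleotides in
#'   lexicographic order, columns = motif position pairs `1..m-1`), or its
#'   transpose (`m - 1` rows of 16), which is detected and flipped.
#' @param name Motif name label.
#' @return An object of class `dipwm` with fields `name`, `m` (motif length
#'   in nucleotides) and `scores` (the 16 x (m-1) matrix).
#' @examples
#' p <- dipwm(matrix(rnorm(16 * 5), nrow = 16), name = "toy")
#' p$m
#' score_word(p, "ACGTAC")
#' @export
dipwm <- function(scores, name = "unnamed") {
  scores <- as.matrix(scores)
  if (ncol(scores) == 16 && nrow(scores) != 16) scores <- t(scores)
  if (nrow(scores) != 16) {
    abort("a di-PWM column must have exactly 16 dinucleotide scores",
          class = "dipwmscan_format_error")
  }
  if (ncol(scores) < 1) {
    abort("a di-PWM needs at least one column (motif length m >= 2)",
          class = "dipwmscan_format_error")
  }
  if (!all(is.finite(scores))) {
    abort("di-PWM scores must all be finite numbers",
          class = "dipwmscan_format_error")
  }
  dimnames(scores) <- list(DINUCLEOTIDES, NULL)
  structure(
    list(name = as.character(name), m = ncol(scores) + 1L, scores = scores),
    class = "dipwm"
  )
}

#' Read a di-PWM from its flat text format
#'
#' The dialect is the HOCOMOCO-style di-PWM layout: an optional `>` header
#' line carrying the motif name, optional `#` comment lines, then `m - 1`
#' rows of 16 whitespace-separated numbers, one row per motif position pair,
#' columns ordered `AA, AC, ..., TT`.
#'
#' @param file Path to a di-PWM text file, or a character vector of lines
#'   (anything with more than one element, or containing a newline, is
#'   treated as content rather than a path).
#' @return A [dipwm] object. The name defaults to `"unnamed"` when no header
#'   is present.
#' @export
read_dipwm <- function(file) {
  lines <- if (length(file) > 1 || grepl("\n", file[1], fixed = TRUE) ||
               !file.exists(file[1])) {
    unlist(strsplit(file, "\n", fixed = TRUE))
  } else {
    readLines(file)
  }
  name <- "unnamed"
  rows <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) {
      name <- trimws(sub("^>", "", ln))
      next
    }
    fields <- strsplit(ln, "[ \t]+")[[1]]
    if (length(fields) != 16) {
      abort(sprintf("line %d: expected 16 scores, found %d",
                    k, length(fields)),
            class = "dipwmscan_format_error")
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      abort(sprintf("line %d: non-numeric score field", k),
            class = "dipwmscan_format_error")
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0) {
    abort("no data rows found in di-PWM input",
          class = "dipwmscan_format_error")
  }
  dipwm(t(do.call(rbind, rows)), name = name)
}

#' Write a di-PWM to its flat text format
#'
#' @param x A [dipwm].
#' @param file Output path.
#' @param digits Number of significant digits for the scores.
#' @return `file`, invisibly.
#' @export
write_dipwm <- function(x, file, digits = 6) {
  stopifnot(inherits(x, "dipwm"))
  rows <- apply(x$scores, 2, function(col) {
    paste(formatC(col, digits = digits, format = "g"), collapse = "\t")
  })
  writeLines(c(paste0(">", x$name), rows), file)
  invisible(file)
}

#' @export
print.dipwm <- function(x, ...) {
  ex <- score_extrema(x)
  cat(sprintf("di-PWM '%s': motif length m = %d (%d columns x 16 dinucleotides)\n",
              x$name, x$m, x$m - 1L))
  cat(sprintf("score range: [%.4g, %.4g]\n", ex[["score_min"]], ex[["score_max"]]))
  invisible(x)
}

#' @describeIn dipwm Long-format view: one row per (position, dinucleotide)
#'   score.
#' @param x,object A `dipwm`.
#' @param ... Unused.
#' @export
tidy.dipwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$m - 1L), each = 16L),
    dinucleotide = rep(DINUCLEOTIDES, x$m - 1L),
    score = as.vector(x$scores)
  )
}

#' @describeIn dipwm One-row summary: name, motif length, score extrema,
#'   column-dispersion range.
#' @export
glance.dipwm <- function(x, ...) {
  ex <- score_extrema(x)
  sds <- column_score_sd(x)
  tibble(
    name = x$name, m = x$m, n_columns = x$m - 1L,
    score_min = ex[["score_min"]], score_max = ex[["score_max"]],
    min_column_sd = min(sds), max_column_sd = max(sds)
  )
}

# Words -> integer letter codes; errors on anything outside ACGT.
word_to_int <- function(word, m = NULL) {
  chars <- split_chars(word)
  if (!is.null(m) && length(chars) != m) {
    abort(sprintf("word '%s' has length %d, motif length is %d",
                  word, length(chars), m),
          class = "dipwmscan_input_error")
  }
  code <- match(chars, DNA_LETTERS)
  if (anyNA(code)) {
    abort(sprintf("word '%s' contains a letter outside ACGT", word),
          class = "dipwmscan_input_error")
  }
  code
}

#' Score DNA words against a di-PWM
#'
#' The score of a word `w` of length `m` is the sum over positions
#' `i = 1..m-1` of the weight of dinucleotide `w[i] w[i+1]` in column `i`.
#'
#' @param x A [dipwm].
#' @param words Character vector of ACGT words, each of length `x$m`.
#' @return Numeric vector of scores, one per word.
#' @export
score_word <- function(x, words) {
  stopifnot(inherits(x, "dipwm"))
  cols <- seq_len(x$m - 1L)
  vapply(words, function(w) {
    code <- word_to_int(w, x$m)
    idx <- 4L * (code[-x$m] - 1L) + code[-1L]
    sum(x$scores[cbind(idx, cols)])
  }, numeric(1), USE.NAMES = FALSE)
}

# Lookahead-style recurrence with a pluggable reducer (max for the LAM proper,
# min for the score minimum). Returns a 4 x m matrix, boundary column m = 0.
lam_table <- function(x, reduce = max) {
  m <- x$m
  tab <- matrix(0, nrow = 4L, ncol = m, dimnames = list(DNA_LETTERS, NULL))
  for (i in seq(m - 1L, 1L)) {
    sq <- matrix(x$scores[, i], nrow = 4L, byrow = TRUE)  # rows alpha, cols beta
    tab[, i] <- apply(sq + matrix(tab[, i + 1L], 4L, 4L, byrow = TRUE), 1L, reduce)
  }
  tab
}

#' LookAhead and LookBack matrices
#'
#' `dipwm_lam(x)[a, i]` is the best achievable score over columns `i..m-1` of
#' any suffix whose first letter, at motif position `i`, is `a`; column `m` is
#' identically zero. `dipwm_lbm(x)[b, i]` is the symmetric best prefix score
#' over columns `1..i-1` for a prefix ending with letter `b` at position `i`;
#' column 1 is zero. Both are built by a dynamic-programming recurrence in
#' O(sigma^2 (m-1)) time, and every entry is realizable: some concrete word
#' attains it. They drive the branch-and-bound pruning in
#' [enumerate_words()] and the early-abandon rule of the window scanner.
#'
#' @param x A [dipwm].
#' @return A 4 x m numeric matrix with rownames A, C, G, T.
#' @export
dipwm_lam <- function(x) {
  stopifnot(inherits(x, "dipwm"))
  lam_table(x, max)
}

#' @rdname dipwm_lam
#' @export
dipwm_lbm <- function(x) {
  stopifnot(inherits(x, "dipwm"))
  m <- x$m
  tab <- matrix(0, nrow = 4L, ncol = m, dimnames = list(DNA_LETTERS, NULL))
  for (i in seq(2L, m)) {
    sq <- matrix(x$scores[, i - 1L], nrow = 4L, byrow = TRUE)
    # entry(beta, i) = max over alpha of entry(alpha, i-1) + P[alpha beta, i-1]
    tab[, i] <- apply(sq + matrix(tab[, i - 1L], 4L, 4L), 2L, max)
  }
  tab
}

# Greedy argmax traceback: the suffix word realizing lam[alpha, i].
lam_traceback <- function(x, lam, alpha, i) {
  m <- x$m
  code <- match(alpha, DNA_LETTERS)
  word <- DNA_LETTERS[code]
  while (i < m) {
    sq <- x$scores[4L * (code - 1L) + seq_len(4L), i]
    nxt <- which.max(sq + lam[, i + 1L])
    word <- paste0(word, DNA_LETTERS[nxt])
    code <- nxt
    i <- i + 1L
  }
  word
}

#' Minimum and maximum achievable di-PWM scores
#'
#' Computed with the lookahead recurrence (max and min variants), never by
#' enumerating the 4^m words.
#'
#' @param x A [dipwm].
#' @return Named numeric vector `c(score_min = , score_max = )`.
#' @export
score_extrema <- function(x) {
  stopifnot(inherits(x, "dipwm"))
  c(score_min = min(lam_table(x, min)[, 1L]),
    score_max = max(lam_table(x, max)[, 1L]))
}
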