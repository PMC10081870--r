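# Independent brute-force oracles. These never call the package's LAM/LBM,
# trie enumeration or scanning code paths: scores come from direct lookups,
# word sets from exhaustive expansion, ambiguous windows from explicit
# product expansion of the disambiguations.

ORACLE_LETTERS <- c("A", "C", "G", "T")

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

ORACLE_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

oracle_revcomp <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  paste(rev(unname(ORACLE_COMPLEMENT[chars])), collapse = "")
}

rand_dipwm <- function(m, sd = 2, name = "rand") {
  dipwm(matrix(rnorm(16 * (m - 1), sd = sd), nrow = 16), name = name)
}

# Direct lookup-and-add score of one word (no vectorization tricks shared
# with the implementation).
oracle_score <- function(x, word) {
  chars <- strsplit(word, "")[[1]]
  s <- 0
  for (i in seq_len(x$m - 1)) {
    d <- paste0(chars[i], chars[i + 1])
    s <- s + x$scores[d, i]
  }
  s
}

# Scores of all 4^m words, in lexicographic order (element j is the word
# with 0-based base-4 index j - 1). Built by extending every word by every
# letter, so it exercises none of the lookahead machinery.
oracle_all_scores <- function(x) {
  m <- x$m
  sc <- rep(0, 4)
  last <- 1:4
  for (i in seq_len(m - 1)) {
    n <- length(sc)
    d <- 4L * (rep(last, each = 4L) - 1L) + rep(1:4, n)
    sc <- rep(sc, each = 4L) + x$scores[cbind(d, i)]
    last <- rep(1:4, n)
  }
  sc
}

oracle_idx_to_word <- function(idx, m) {
  vapply(idx, function(v) {
    letters <- integer(m)
    for (p in m:1) {
      letters[p] <- v %% 4
      v <- v %/% 4
    }
    paste(ORACLE_LETTERS[letters + 1], collapse = "")
  }, character(1))
}

oracle_word_to_idx <- function(words) {
  vapply(words, function(w) {
    sum((match(strsplit(w, "")[[1]], ORACLE_LETTERS) - 1) *
          4^((nchar(w) - 1):0))
  }, numeric(1), USE.NAMES = FALSE)
}

# Valid words by exhaustive filtering, under the same 1e-9 threshold
# tolerance the package documents.
oracle_valid_words <- function(x, t) {
  sc <- oracle_all_scores(x)
  keep <- which(sc >= t - 1e-9)
  list(idx = keep - 1, score = sc[keep])
}

# Best disambiguation of a window by explicit product expansion.
oracle_window_best <- function(x, chars) {
  sets <- ORACLE_IUPAC[chars]
  stopifnot(prod(lengths(sets)) <= 5000)
  combos <- expand.grid(sets, stringsAsFactors = FALSE)
  words <- do.call(paste0, combos)
  scores <- vapply(words, function(w) oracle_score(x, w), numeric(1))
  j <- which.max(scores)
  list(score = scores[[j]], word = words[[j]])
}

# All-windows scan of one sequence orientation: every window scored, pure
# windows by direct summation (vectorized over starts), ambiguous windows by
# product expansion. Returns start, word, score, ambiguous for score >= t.
oracle_scan_one <- function(x, seq, t) {
  chars <- strsplit(seq, "")[[1]]
  m <- x$m
  n <- length(chars)
  if (n < m) {
    return(data.frame(start = integer(), word = character(),
                      score = numeric(), ambiguous = logical()))
  }
  ints <- match(chars, ORACLE_LETTERS)  # NA at ambiguity codes
  starts <- seq_len(n - m + 1)
  amb <- vapply(starts, function(s) anyNA(ints[s:(s + m - 1)]), logical(1))
  out <- list()
  ps <- starts[!amb]
  if (length(ps)) {
    sc <- numeric(length(ps))
    for (j in seq_len(m - 1)) {
      d <- 4L * (ints[ps + j - 1] - 1L) + ints[ps + j]
      sc <- sc + x$scores[cbind(d, j)]
    }
    keep <- sc >= t - 1e-9
    out$pure <- data.frame(
      start = ps[keep],
      word = vapply(ps[keep], function(s) paste(chars[s:(s + m - 1)],
                                                collapse = ""), character(1)),
      score = sc[keep], ambiguous = rep(FALSE, sum(keep)))
  }
  for (s in starts[amb]) {
    bw <- oracle_window_best(x, chars[s:(s + m - 1)])
    if (bw$score >= t - 1e-9) {
      out[[length(out) + 1]] <- data.frame(
        start = s, word = bw$word, score = bw$score, ambiguous = TRUE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(start = integer(), word = character(),
                      score = numeric(), ambiguous = logical())
  }
  res[order(res$start), , drop = FALSE]
}

# Full two-strand oracle matching the pipeline's output contract.
oracle_search <- function(x, sequences, t, strands = "both") {
  out <- list()
  for (i in seq_len(nrow(sequences))) {
    sq <- sequences$seq[i]
    L <- nchar(sq)
    fwd <- oracle_scan_one(x, sq, t)
    if (nrow(fwd)) {
      fwd$seq_id <- sequences$seq_id[i]
      fwd$strand <- "+"
      out[[length(out) + 1]] <- fwd
    }
    if (strands == "both") {
      rev <- oracle_scan_one(x, oracle_revcomp(sq), t)
      if (nrow(rev)) {
        rev$start <- L - (rev$start + x$m - 1) + 1
        rev$seq_id <- sequences$seq_id[i]
        rev$strand <- "-"
        out[[length(out) + 1]] <- rev
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(seq_id = character(), start = integer(),
                      strand = character(), word = character(),
                      score = numeric(), ambiguous = logical()))
  }
  res <- res[order(res$seq_id, res$start, res$strand), ]
  rownames(res) <- NULL
  res[, c("seq_id", "start", "strand", "word", "score", "ambiguous")]
}

# Random ACGT string, optionally with ambiguity codes sprinkled in.
rand_seq <- function(n, iupac_rate = 0) {
  chars <- sample(ORACLE_LETTERS, n, replace = TRUE)
  if (iupac_rate > 0) {
    k <- which(runif(n) < iupac_rate)
    codes <- setdiff(names(ORACLE_IUPAC), ORACLE_LETTERS)
    chars[k] <- sample(codes, length(k), replace = TRUE)
  }
  paste(chars, collapse = "")
}

# Same (seq_id, start, strand) set with equal scores. Words must agree on
# unambiguous windows; on ambiguous windows two correct implementations may
# report different maximizing disambiguations when scores tie, so only the
# scores are compared there.
expect_same_occurrences <- function(a, b, tol = 1e-9) {
  cols <- c("seq_id", "start", "strand", "word", "score", "ambiguous")
  a <- as.data.frame(a)[, cols]
  b <- as.data.frame(b)[, cols]
  a$start <- as.integer(a$start)
  b$start <- as.integer(b$start)
  a <- a[order(a$seq_id, a$start, a$strand), ]
  b <- b[order(b$seq_id, b$start, b$strand), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(nrow(a), nrow(b))
  if (nrow(a)) {
    expect_identical(a[, c("seq_id", "start", "strand")],
                     b[, c("seq_id", "start", "strand")])
    expect_lt(max(abs(a$score - b$score)), tol)
    pure <- !a$ambiguous & !b$ambiguous
    expect_identical(a$word[pure], b$word[pure])
  }
}
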