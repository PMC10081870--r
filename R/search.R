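#' Multi-pattern matcher over a set of equal-length words
#'
#' Wraps a constant-width dictionary matcher (Biostrings preprocessed
#' dictionary) that reports, in a single left-to-right pass over a text,
#' every occurrence of every word; construction is linear in the cumulated
#' word length. An empty word set gives a matcher that never fires.
#'
#' @param words Character vector of distinct, equal-length ACGT words, or a
#'   tibble with a `word` column (as produced by [enumerate_words()]).
#' @return A `dipwm_matcher` object.
#' @export
dipwm_matcher <- function(words) {
  if (is.data.frame(words)) words <- words$word
  words <- as.character(words)
  if (length(words) > 0) {
    w <- unique(nchar(words))
    if (length(w) != 1) {
      abort("matcher words must all have equal length",
            class = "dipwmscan_input_error")
    }
    pdict <- Biostrings::PDict(Biostrings::DNAStringSet(words))
  } else {
    w <- 0L
    pdict <- NULL
  }
  structure(
    list(words = words, width = as.integer(w), pdict = pdict,
         cache = new.env(parent = emptyenv())),
    class = "dipwm_matcher"
  )
}

#' @export
print.dipwm_matcher <- function(x, ...) {
  cat(sprintf("di-PWM word matcher: %d words of width %d\n",
              length(x$words), x$width))
  invisible(x)
}

# Word letters as IUPAC bitmasks, one row per word; built on first use.
matcher_wbits <- function(matcher) {
  if (is.null(matcher$cache$wbits)) {
    matcher$cache$wbits <- matrix(
      IUPAC_MASKS[unlist(strsplit(matcher$words, "", fixed = TRUE))],
      nrow = length(matcher$words), byrow = TRUE
    )
  }
  matcher$cache$wbits
}

check_sequence <- function(chars, seq_id = "sequence") {
  bad <- which(!(chars %in% names(IUPAC_MASKS)))
  if (length(bad)) {
    abort(sprintf("%s: symbol '%s' at position %d is not an IUPAC nucleotide code",
                  seq_id, chars[bad[1]], bad[1]),
          class = "dipwmscan_input_error")
  }
  invisible(chars)
}

#' Locate dictionary words in an ACGT sequence
#'
#' `scan_exact()` requires a plain ACGT text and reports every exact
#' occurrence. `scan_iupac()` accepts the 15-letter IUPAC alphabet and
#' reports a word at a position whenever *some* disambiguation of the window
#' (one letter from each code's set) equals the word; on ACGT-only text it
#' reduces exactly to `scan_exact()`.
#'
#' @param matcher A [dipwm_matcher()].
#' @param seq A single sequence string (uppercase).
#' @return A tibble with columns `start` (1-based) and `word`, ordered by
#'   start then word.
#' @export
scan_exact <- function(matcher, seq) {
  stopifnot(inherits(matcher, "dipwm_matcher"))
  chars <- split_chars(seq)
  check_sequence(chars)
  if (any(!(chars %in% DNA_LETTERS))) {
    abort("scan_exact() requires a plain ACGT sequence; use scan_iupac()",
          class = "dipwmscan_input_error")
  }
  scan_pdict(matcher, seq)
}

scan_pdict <- function(matcher, seq) {
  if (length(matcher$words) == 0 || nchar(seq) < matcher$width) {
    return(tibble(start = integer(), word = character()))
  }
  hits <- Biostrings::matchPDict(matcher$pdict, Biostrings::DNAString(seq))
  si <- Biostrings::startIndex(hits)
  out <- tibble(start = as.integer(unlist(si)),
                word = rep(matcher$words, lengths(si)))
  dplyr::arrange(out, .data$start, .data$word)
}

#' @rdname scan_exact
#' @export
scan_iupac <- function(matcher, seq) {
  stopifnot(inherits(matcher, "dipwm_matcher"))
  chars <- split_chars(seq)
  check_sequence(chars)
  # Exact matches: ambiguity codes in the subject never match an ACGT
  # pattern letter, so the dictionary pass finds precisely the pure windows.
  out <- scan_pdict(matcher, seq)
  ints <- seq_to_int(chars)
  astarts <- amb_window_starts(ints, matcher$width)
  if (length(astarts) && length(matcher$words)) {
    masks <- seq_to_mask(chars)
    wbits <- matcher_wbits(matcher)
    n <- nrow(wbits)
    amb <- purrr::map_dfr(astarts, function(p) {
      v <- masks[p:(p + matcher$width - 1L)]
      miss <- matrix(bitwAnd(as.vector(wbits), rep(v, each = n)) == 0L, nrow = n)
      ok <- rowSums(miss) == 0
      tibble(start = rep(p, sum(ok)), word = matcher$words[ok])
    })
    out <- dplyr::arrange(dplyr::bind_rows(out, amb), .data$start, .data$word)
  }
  out
}

# Starts of all length-len windows that contain at least one ambiguity code.
amb_window_starts <- function(ints, len) {
  amb <- which(ints == 0L)
  if (!length(amb)) return(integer())
  n <- length(ints)
  from <- pmax(1L, amb - len + 1L)
  to <- pmin(amb, n - len + 1L)
  keep <- from <= to
  if (!any(keep)) return(integer())
  sort(unique(unlist(Map(seq.int, from[keep], to[keep]))))
}

# Best-disambiguation score of one window, with the maximizing word.
# masks: m IUPAC bitmasks. Dynamic program over (position, letter) states,
# O(m * 16); never expands the product of disambiguations.
score_window_best <- function(x, masks) {
  m <- x$m
  lbits <- c(1L, 2L, 4L, 8L)
  best <- ifelse(bitwAnd(masks[1L], lbits) != 0L, 0, -Inf)
  back <- matrix(NA_integer_, nrow = m, ncol = 4L)
  for (i in 2:m) {
    newbest <- rep(-Inf, 4L)
    for (b in which(bitwAnd(masks[i], lbits) != 0L)) {
      cand <- best + x$scores[4L * 0:3 + b, i - 1L]
      j <- which.max(cand)
      if (cand[j] > -Inf) {
        newbest[b] <- cand[j]
        back[i, b] <- j
      }
    }
    best <- newbest
  }
  b <- which.max(best)
  letters <- integer(m)
  letters[m] <- b
  for (i in m:2) letters[i - 1L] <- back[i, letters[i]]
  list(score = best[b], word = paste(DNA_LETTERS[letters], collapse = ""))
}

# Exact scores of pure-ACGT windows at the given starts, vectorized.
score_windows_at <- function(x, ints, starts) {
  sc <- numeric(length(starts))
  for (j in seq_len(x$m - 1L)) {
    a <- ints[starts + j - 1L]
    b <- ints[starts + j]
    sc <- sc + x$scores[cbind(4L * (a - 1L) + b, j)]
  }
  sc
}

# Score candidate full-motif windows at the given starts and keep those
# reaching t. Pure windows are scored exactly; windows containing ambiguity
# codes get their best-disambiguation score and are flagged.
rescore_windows <- function(x, chars, ints, starts, t) {
  m <- x$m
  n <- length(ints)
  starts <- sort(unique(starts))
  starts <- starts[starts >= 1L & starts + m - 1L <= n]
  if (!length(starts)) {
    return(tibble(start = integer(), word = character(),
                  score = numeric(), ambiguous = logical()))
  }
  ambpos <- which(ints == 0L)
  is_amb <- if (length(ambpos)) {
    vapply(starts, function(s) any(ambpos >= s & ambpos <= s + m - 1L),
           logical(1))
  } else rep(FALSE, length(starts))

  res <- vector("list", 2L)
  if (any(!is_amb)) {
    ps <- starts[!is_amb]
    res[[1]] <- tibble(
      start = ps,
      word = vapply(ps, function(s) paste(chars[s:(s + m - 1L)], collapse = ""),
                    character(1)),
      score = score_windows_at(x, ints, ps),
      ambiguous = FALSE
    )
  }
  if (any(is_amb)) {
    masks_all <- seq_to_mask(chars)
    res[[2]] <- purrr::map_dfr(starts[is_amb], function(s) {
      bs <- score_window_best(x, masks_all[s:(s + m - 1L)])
      tibble(start = s, word = bs$word, score = bs$score, ambiguous = TRUE)
    })
  }
  out <- dplyr::bind_rows(res)
  dplyr::arrange(out[out$score >= t - SCORE_TOL, ], .data$start)
}

#' Rescore core-word hits into full-motif occurrences
#'
#' A core hit starting at sequence position `p` proposes the full window
#' starting at `s = p - k` (where `k` is the core offset); windows truncated
#' by the sequence ends are discarded, duplicate windows reached through
#' different core hits are scored once, and an occurrence is kept when the
#' full-matrix window score reaches the threshold.
#'
#' @param x A [dipwm].
#' @param core The [select_core()] interval the hits came from.
#' @param seq The sequence string the hits refer to.
#' @param hits A tibble with a `start` column of core-hit positions
#'   (1-based), e.g. from [scan_iupac()].
#' @param t Resolved score threshold.
#' @return A tibble with columns `start`, `word`, `score`, `ambiguous`.
#' @export
rescore_core_hits <- function(x, core, seq, hits, t) {
  stopifnot(inherits(x, "dipwm"), inherits(core, "dipwm_core"))
  chars <- split_chars(seq)
  check_sequence(chars)
  rescore_windows(x, chars, seq_to_int(chars), hits$start - core$k, t)
}

#' Lookahead-pruned window scanner
#'
#' Scores every length-`m` window of the sequence, accumulating column
#' scores left to right and abandoning a window as soon as the running
#' partial score plus the best realizable suffix score (LookAhead matrix)
#' falls below the threshold. Emits exactly the windows a full scan would,
#' with identical scores; windows containing IUPAC codes are scored by the
#' same best-disambiguation rule as [rescore_core_hits()].
#'
#' @inheritParams rescore_core_hits
#' @param seq Sequence string over the IUPAC alphabet.
#' @return A tibble with columns `start`, `word`, `score`, `ambiguous`.
#' @export
scan_os <- function(x, seq, t) {
  stopifnot(inherits(x, "dipwm"))
  chars <- split_chars(seq)
  check_sequence(chars)
  ints <- seq_to_int(chars)
  res <- cpp_scan_os(ints, x$scores, dipwm_lam(x), x$m, t - SCORE_TOL)
  pure <- tibble(
    start = res$start,
    word = vapply(res$start,
                  function(s) paste(chars[s:(s + x$m - 1L)], collapse = ""),
                  character(1)),
    score = res$score,
    ambiguous = FALSE
  )
  pure <- pure[pure$score >= t - SCORE_TOL, ]
  if (length(res$amb_start)) {
    masks <- seq_to_mask(chars)
    ambo <- purrr::map_dfr(unique(res$amb_start), function(s) {
      bs <- score_window_best(x, masks[s:(s + x$m - 1L)])
      tibble(start = s, word = bs$word, score = bs$score, ambiguous = TRUE)
    })
    pure <- dplyr::bind_rows(pure, ambo[ambo$score >= t, ])
  }
  dplyr::arrange(pure, .data$start)
}

# Normalize the accepted sequence inputs to a tibble(seq_id, seq).
as_sequences <- function(sequences) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("seq_id", "seq") %in% names(sequences)))
    return(tibble(seq_id = as.character(sequences$seq_id),
                  seq = toupper(as.character(sequences$seq))))
  }
  if (inherits(sequences, "XStringSet")) {
    return(tibble(seq_id = names(sequences), seq = as.character(sequences)))
  }
  if (is.character(sequences)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
    return(tibble(seq_id = ids, seq = toupper(unname(sequences))))
  }
  abort("sequences must be a tibble(seq_id, seq), a named character vector or a DNAStringSet",
        class = "dipwmscan_input_error")
}

# One sequence, one orientation. Returns tibble(start, word, score, ambiguous)
# in the scanned orientation's coordinates.
search_engine <- function(x, seq, t, algorithm, matcher = NULL, core = NULL) {
  chars <- split_chars(seq)
  check_sequence(chars)
  if (nchar(seq) < x$m) {
    return(tibble(start = integer(), word = character(),
                  score = numeric(), ambiguous = logical()))
  }
  if (algorithm == "os") return(scan_os(x, seq, t))
  k <- if (algorithm == "ce") core$k else 0L
  hits <- scan_iupac(matcher, seq)
  rescore_windows(x, chars, seq_to_int(chars), hits$start - k, t)
}

#' Search sequences for di-PWM occurrences
#'
#' The top-level pipeline. Resolves the threshold, then dispatches to one of
#' three equivalent algorithms:
#' * `"ce"` (core enumeration, the default): select the high-selectivity
#'   core, enumerate core words whose best full-length extension can reach
#'   the threshold, locate them with the multi-pattern matcher, and rescore
#'   each candidate full window against the whole matrix;
#' * `"fe"` (full enumeration): enumerate all valid full-length words and
#'   locate them directly;
#' * `"os"`: lookahead-pruned window scanning, no enumeration (the fallback
#'   when the word set would explode).
#'
#' The reverse strand is searched by scanning each sequence's IUPAC-aware
#' reverse complement and mapping coordinates back to the forward strand.
#' All three algorithms return identical occurrence sets.
#'
#' @param sequences A tibble with columns `seq_id` and `seq`, a named
#'   character vector, or a `DNAStringSet` (see [read_fasta()]).
#' @param x A [dipwm].
#' @param threshold A [threshold_score()]/[threshold_ratio()]/
#'   [threshold_pvalue()] spec, or a bare absolute score.
#' @param algorithm `"ce"`, `"fe"` or `"os"`.
#' @param strands `"both"` (default) or `"forward"`.
#' @param core Optional precomputed [select_core()] interval (CE only).
#' @param min_cols Minimum core width passed to [select_core()].
#' @param dist Optional [score_distribution()] for P-value thresholds and
#'   annotation; computed on demand from `background`/`granularity` when a
#'   P-value threshold is given.
#' @param background,granularity Background letter frequencies and score
#'   bin width used when a distribution has to be computed.
#' @param cap Valid-word cap forwarded to the enumerators.
#' @return A tibble of occurrences with columns `seq_id`, `start`, `end`
#'   (1-based inclusive), `strand`, `word` (the scored ACGT word; for
#'   ambiguous windows the maximizing disambiguation), `score` and
#'   `ambiguous`, sorted by (seq_id, start, strand). Attributes `threshold`
#'   (resolved score), `dipwm_name` and `algorithm` are attached.
#' @examples
#' p <- synthetic_dipwm(8, seed = 1)
#' d <- synthetic_dataset(p, n_seq = 2, seq_len = 400, n_planted = 3, seed = 2)
#' search_dipwm(d$sequences, p, threshold_ratio(0.9))
#' @export
search_dipwm <- function(sequences, x, threshold,
                         algorithm = c("ce", "fe", "os"),
                         strands = c("both", "forward"),
                         core = NULL, min_cols = 10, dist = NULL,
                         background = uniform_background(),
                         granularity = 1e-3, cap = 5e6) {
  stopifnot(inherits(x, "dipwm"))
  algorithm <- match.arg(algorithm)
  strands <- match.arg(strands)
  seqs <- as_sequences(sequences)
  spec <- as_threshold(threshold)
  if (spec$mode == "pvalue" && is.null(dist)) {
    dist <- score_distribution(x, background = background,
                               granularity = granularity)
  }
  t <- resolve_threshold(x, spec, dist)

  matcher <- NULL
  if (algorithm == "fe") {
    matcher <- dipwm_matcher(enumerate_words(x, t, cap = cap))
  } else if (algorithm == "ce") {
    if (is.null(core)) core <- select_core(x, min_cols = min_cols)
    matcher <- dipwm_matcher(enumerate_core_words(x, t, core = core, cap = cap))
  }

  strand_set <- if (strands == "both") c("+", "-") else "+"
  out <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    sq <- seqs$seq[i]
    L <- nchar(sq)
    purrr::map_dfr(strand_set, function(st) {
      scanned <- if (st == "+") sq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
      occ <- search_engine(x, scanned, t, algorithm, matcher, core)
      if (nrow(occ) == 0) return(occ[0, ])
      start_fwd <- if (st == "+") occ$start else L - (occ$start + x$m - 1L) + 1L
      tibble(seq_id = seqs$seq_id[i], start = start_fwd,
             end = start_fwd + x$m - 1L, strand = st,
             word = occ$word, score = occ$score, ambiguous = occ$ambiguous)
    })
  })
  if (nrow(out) == 0) {
    out <- tibble(seq_id = character(), start = integer(), end = integer(),
                  strand = character(), word = character(), score = numeric(),
                  ambiguous = logical())
  }
  out <- dplyr::distinct(dplyr::arrange(out, .data$seq_id, .data$start,
                                        .data$strand))
  attr(out, "threshold") <- t
  attr(out, "dipwm_name") <- x$name
  attr(out, "algorithm") <- algorithm
  out
}
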