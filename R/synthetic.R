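#' Generate a random synthetic di-PWM
#'
#' Each column's 16 dinucleotide scores are log2 ratios of
#' Dirichlet-sampled dinucleotide frequencies against the uniform 1/16,
#' mimicking the log-odds-style weights of database di-PWMs. Small
#' concentration values give peaked (selective) columns; large values give
#' flat (nonselective) ones.
#'
#' @param m Motif length in nucleotides (>= 2).
#' @param concentration Dirichlet concentration per dinucleotide
#'   (default 0.5).
#' @param seed Optional integer seed for reproducibility.
#' @param name Motif name.
#' @return A [dipwm].
#' @export
synthetic_dipwm <- function(m, concentration = 0.5, seed = NULL,
                            name = "synthetic") {
  stopifnot(m >= 2)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  cols <- vapply(seq_len(m - 1L), function(i) {
    g <- rgamma(16L, shape = concentration, rate = 1)
    g[g < 1e-12] <- 1e-12
    p <- g / sum(g)
    log2(p / (1 / 16))
  }, numeric(16L))
  dipwm(matrix(cols, nrow = 16L), name = name)
}

# Seed handling: scoped RNG state so generators are deterministic under a
# seed but never clobber the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate sequences with planted di-PWM occurrences
#'
#' Background sequences of i.i.d. uniform ACGT letters, with high-scoring
#' valid words (enumerated at the `plant_ratio` ratio threshold) planted at
#' recorded non-overlapping positions. Optionally, letters inside planted
#' words are replaced, at rate `iupac_rate`, by a random IUPAC ambiguity
#' code whose set contains the planted letter, so every planted word
#' remains recoverable under exists-disambiguation matching.
#'
#' @param x A [dipwm].
#' @param n_seq Number of sequences.
#' @param seq_len Length of each sequence (nucleotides).
#' @param n_planted Total number of planted occurrences, spread round-robin
#'   over the sequences.
#' @param iupac_rate Per-letter probability of ambiguity-code injection
#'   inside planted words, in `[0, 1]`.
#' @param plant_ratio Ratio threshold from which planted words are drawn
#'   (default 0.97: near-maximal scorers).
#' @param seed Optional integer seed.
#' @param cap Valid-word cap for the enumeration of plantable words.
#' @return A list with `sequences` (tibble `seq_id`, `seq`, `length`) and
#'   `truth` (tibble `seq_id`, `start`, `word`: the planted occurrences,
#'   forward strand).
#' @export
synthetic_dataset <- function(x, n_seq = 1, seq_len = 1000, n_planted = 0,
                              iupac_rate = 0, plant_ratio = 0.97,
                              seed = NULL, cap = 5e6) {
  stopifnot(inherits(x, "dipwm"), n_seq >= 1, seq_len >= 1,
            n_planted >= 0, iupac_rate >= 0, iupac_rate <= 1)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  m <- x$m
  pool <- if (n_planted > 0) {
    enumerate_words(x, threshold_ratio(plant_ratio), cap = cap)$word
  } else character()

  seq_ids <- sprintf("synth_seq_%02d", base::seq_len(n_seq))
  chars <- lapply(base::seq_len(n_seq), function(i) {
    sample(DNA_LETTERS, seq_len, replace = TRUE)
  })
  truth <- tibble(seq_id = character(), start = integer(), word = character())

  if (n_planted > 0) {
    if (seq_len < m) {
      abort("sequences are shorter than the motif; cannot plant occurrences",
            class = "dipwmscan_input_error")
    }
    target <- rep(base::seq_len(n_seq), length.out = n_planted)
    for (i in base::seq_len(n_seq)) {
      want <- sum(target == i)
      if (want == 0) next
      placed <- integer()
      tries <- 0L
      while (length(placed) < want) {
        tries <- tries + 1L
        if (tries > 200L * want) {
          abort("could not place non-overlapping occurrences; use longer sequences",
                class = "dipwmscan_input_error")
        }
        s <- sample.int(seq_len - m + 1L, 1L)
        if (any(abs(placed - s) < m)) next
        placed <- c(placed, s)
      }
      placed <- sort(placed)
      words <- sample(pool, want, replace = TRUE)
      for (j in seq_along(placed)) {
        s <- placed[j]
        wchars <- split_chars(words[j])
        if (iupac_rate > 0) {
          inject <- runif(m) < iupac_rate
          for (pidx in which(inject)) {
            compat <- names(IUPAC_MASKS)[
              bitwAnd(IUPAC_MASKS, IUPAC_MASKS[wchars[pidx]]) != 0L &
                IUPAC_MASKS != IUPAC_MASKS[wchars[pidx]]]
            wchars_code <- sample(compat, 1L)
            chars[[i]][s + pidx - 1L] <- wchars_code
          }
          pure <- which(!inject)
          chars[[i]][s + pure - 1L] <- wchars[pure]
        } else {
          chars[[i]][s:(s + m - 1L)] <- wchars
        }
        truth <- dplyr::bind_rows(truth, tibble(
          seq_id = seq_ids[i], start = s, word = words[j]))
      }
    }
  }
  seqs <- vapply(chars, paste, character(1), collapse = "")
  list(
    sequences = tibble(seq_id = seq_ids, seq = seqs, length = nchar(seqs)),
    truth = dplyr::arrange(truth, .data$seq_id, .data$start)
  )
}

#' Write a complete synthetic fixture to disk
#'
#' Emits a di-PWM text file, a FASTA of sequences with planted occurrences,
#' and a truth TSV of the planted (seq_id, start, word) rows. Deterministic
#' under `seed`.
#'
#' @inheritParams synthetic_dataset
#' @param dir Output directory (created if missing).
#' @param m,concentration Passed to [synthetic_dipwm()].
#' @return Named list of the three file paths (`dipwm`, `fasta`, `truth`),
#'   plus the generated objects (`x`, `dataset`).
#' @export
generate_fixture <- function(dir, m = 12, concentration = 0.5, n_seq = 2,
                             seq_len = 2000, n_planted = 6, iupac_rate = 0,
                             plant_ratio = 0.97, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- synthetic_dipwm(m, concentration = concentration, seed = seed,
                       name = sprintf("SYNTH_M%d_S%d", m, seed))
  ds <- synthetic_dataset(x, n_seq = n_seq, seq_len = seq_len,
                          n_planted = n_planted, iupac_rate = iupac_rate,
                          plant_ratio = plant_ratio, seed = seed + 1L)
  paths <- list(dipwm = file.path(dir, "motif.dpwm"),
                fasta = file.path(dir, "sequences.fa"),
                truth = file.path(dir, "truth.tsv"))
  write_dipwm(x, paths$dipwm, digits = 10)
  write_fasta(ds$sequences, paths$fasta)
  write.table(ds$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(paths, list(x = x, dataset = ds))
}
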