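# Multi-pattern matching, IUPAC semantics, rescoring, the window scanner,
# and the full pipeline equivalences.

test_that("the matcher reports every occurrence of every word", {
  m <- dipwm_matcher("ACG")
  hits <- scan_exact(m, "TACGA")
  expect_equal(hits$start, 2L)          # ACG ends at position 4
  expect_equal(hits$word, "ACG")

  m2 <- dipwm_matcher(c("AA", "AT"))
  hits2 <- scan_exact(m2, "AAAT")
  expect_equal(hits2$start, c(1L, 2L, 3L))
  expect_equal(hits2$word, c("AA", "AA", "AT"))

  expect_equal(nrow(scan_exact(m2, "")), 0)
  expect_equal(nrow(scan_exact(dipwm_matcher(character()), "ACGT")), 0)

  expect_error(dipwm_matcher(c("AA", "ACG")), class = "dipwmscan_input_error")
})

test_that("exact scanning equals a naive substring oracle on random text", {
  set.seed(107)
  words <- unique(replicate(8, paste(sample(c("A", "C", "G", "T"), 4, TRUE),
                                     collapse = "")))
  mt <- dipwm_matcher(words)
  txt <- rand_seq(600)
  hits <- scan_exact(mt, txt)
  naive <- do.call(rbind, lapply(seq_len(nchar(txt) - 3), function(s) {
    win <- substr(txt, s, s + 3)
    if (win %in% words) data.frame(start = s, word = win) else NULL
  }))
  expect_equal(hits$start, naive$start)
  expect_equal(hits$word, naive$word)
})

test_that("IUPAC scanning uses exists-disambiguation semantics", {
  m <- dipwm_matcher("ACG")
  expect_equal(scan_iupac(m, "ANG")$start, 1L)    # N covers C
  expect_equal(scan_iupac(m, "AYG")$start, 1L)    # Y = {C,T} covers C
  expect_equal(nrow(scan_iupac(m, "ARG")), 0)     # R = {A,G} excludes C

  m4 <- dipwm_matcher("AAAA")
  expect_equal(scan_iupac(m4, "NNNN")$start, 1L)

  expect_error(scan_iupac(m, "AC*"), "position 3",
               class = "dipwmscan_input_error")
  expect_error(scan_exact(m, "ANG"), class = "dipwmscan_input_error")
})

test_that("IUPAC scanning reduces to exact scanning on plain ACGT text", {
  set.seed(109)
  words <- unique(replicate(10, paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                                      collapse = "")))
  mt <- dipwm_matcher(words)
  txt <- rand_seq(800)
  expect_identical(scan_iupac(mt, txt), scan_exact(mt, txt))
})

test_that("IUPAC hits agree with a per-position set-membership oracle", {
  set.seed(113)
  words <- unique(replicate(12, paste(sample(c("A", "C", "G", "T"), 4, TRUE),
                                      collapse = "")))
  mt <- dipwm_matcher(words)
  txt <- rand_seq(300, iupac_rate = 0.05)
  hits <- scan_iupac(mt, txt)
  chars <- strsplit(txt, "")[[1]]
  naive <- list()
  for (s in seq_len(nchar(txt) - 3)) {
    sets <- ORACLE_IUPAC[chars[s:(s + 3)]]
    for (w in words) {
      wl <- strsplit(w, "")[[1]]
      if (all(mapply(function(l, st) l %in% st, wl, sets))) {
        naive[[length(naive) + 1]] <- data.frame(start = s, word = w)
      }
    }
  }
  naive <- do.call(rbind, naive)
  naive <- naive[order(naive$start, naive$word), ]
  expect_equal(hits$start, naive$start)
  expect_equal(hits$word, naive$word)
})

test_that("core hits rescore into full-window occurrences", {
  set.seed(127)
  p <- rand_dipwm(6)
  t <- resolve_threshold(p, threshold_ratio(0.8))
  txt <- rand_seq(400)

  # full-matrix core: rescoring is the identity check on direct matches
  full_core <- dipwmscan:::new_core(1, p$m - 1, 0)
  words <- enumerate_words(p, t)
  hits <- scan_exact(dipwm_matcher(words), txt)
  occ <- rescore_core_hits(p, full_core, txt, hits, t)
  naive <- oracle_scan_one(p, txt, t)
  expect_equal(occ$start, naive$start)
  expect_equal(occ$score, naive$score, tolerance = 1e-9)

  # windows pushed before the sequence start are discarded
  core_off <- dipwmscan:::new_core(3, p$m - 1, 0)  # k = 2
  occ2 <- rescore_core_hits(p, core_off, txt,
                            data.frame(start = c(1L, 2L, 5L)), -1e9)
  expect_equal(occ2$start, 3L)   # only the core hit at 5 yields a full window
})

test_that("the lookahead scanner matches the naive scan exactly", {
  set.seed(131)
  p <- rand_dipwm(7)
  ex <- score_extrema(p)
  txt <- rand_seq(500)

  # threshold at the minimum: every window comes out
  all_w <- scan_os(p, txt, ex[["score_min"]])
  expect_equal(nrow(all_w), nchar(txt) - p$m + 1)

  # threshold above the maximum: nothing comes out
  expect_equal(nrow(scan_os(p, txt, ex[["score_max"]] + 1)), 0)

  for (r in c(0.7, 0.9)) {
    t <- resolve_threshold(p, threshold_ratio(r))
    got <- scan_os(p, txt, t)
    want <- oracle_scan_one(p, txt, t)
    expect_equal(got$start, want$start)
    expect_equal(got$score, want$score, tolerance = 1e-9)
    expect_identical(got$word, want$word)
  }
})

test_that("CE, FE, OS and the naive scan agree on random instances", {
  set.seed(137)
  for (rep in 1:4) {
    m <- sample(6:9, 1)
    p <- rand_dipwm(m)
    seqs <- tibble::tibble(
      seq_id = c("s1", "s2"),
      seq = c(rand_seq(700, iupac_rate = 0.01), rand_seq(500)))
    t <- resolve_threshold(p, threshold_ratio(sample(c(0.75, 0.85, 0.9), 1)))
    want <- oracle_search(p, seqs, t, strands = "both")
    for (alg in c("ce", "fe", "os")) {
      got <- search_dipwm(seqs, p, t, algorithm = alg)
      expect_same_occurrences(got, want)
      expect_true(all(got$score >= t - 1e-9))
    }
  }
})

test_that("a planted maximal word is found at its position by every algorithm", {
  set.seed(139)
  p <- rand_dipwm(8)
  lam <- dipwm_lam(p)
  best_word <- dipwmscan:::lam_traceback(
    p, lam, c("A", "C", "G", "T")[which.max(lam[, 1])], 1)
  expect_equal(score_word(p, best_word), score_extrema(p)[["score_max"]],
               tolerance = 1e-12)
  txt <- rand_seq(300)
  substr(txt, 101, 108) <- best_word
  seqs <- tibble::tibble(seq_id = "planted", seq = txt)
  t <- resolve_threshold(p, threshold_ratio(0.95))
  for (alg in c("ce", "fe", "os")) {
    got <- search_dipwm(seqs, p, t, algorithm = alg)
    row <- got[got$start == 101 & got$strand == "+", ]
    expect_equal(nrow(row), 1)
    expect_equal(row$word, best_word)
    expect_equal(row$score, score_extrema(p)[["score_max"]], tolerance = 1e-9)
  }
})

test_that("reverse-strand scores equal forward scores of the reverse complement", {
  set.seed(149)
  p <- rand_dipwm(6)
  txt <- rand_seq(400)
  t <- resolve_threshold(p, threshold_ratio(0.8))
  occ <- search_dipwm(tibble::tibble(seq_id = "s", seq = txt), p, t)
  minus <- occ[occ$strand == "-", ]
  for (i in seq_len(nrow(minus))) {
    win <- substr(txt, minus$start[i], minus$end[i])
    expect_equal(score_word(p, oracle_revcomp(win)), minus$score[i],
                 tolerance = 1e-9)
    expect_identical(oracle_revcomp(win), minus$word[i])
  }

  # a palindromic match is reported once per strand with equal scores
  pal <- dipwm(matrix(0, 16, 3), "pal")        # every word scores 0
  seqs <- tibble::tibble(seq_id = "s", seq = "ACGT")
  both <- search_dipwm(seqs, pal, 0, algorithm = "os")
  expect_equal(sum(both$strand == "+"), 1)
  expect_equal(sum(both$strand == "-"), 1)
  expect_equal(both$score, c(0, 0))
})

test_that("the pipeline propagates resource errors from enumeration", {
  p <- dipwm(matrix(0, 16, 5), "flat")
  seqs <- tibble::tibble(seq_id = "s", seq = rand_seq(50))
  expect_error(search_dipwm(seqs, p, 0, algorithm = "fe", cap = 10),
               class = "dipwmscan_resource_error")
})
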