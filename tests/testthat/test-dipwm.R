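# di-PWM construction, parsing, scoring, extrema, thresholds, LAM/LBM.

zero_dipwm <- function(m) dipwm(matrix(0, nrow = 16, ncol = m - 1), "zero")

test_that("the flat text format parses headers, comments and data rows", {
  txt <- c(">X", paste(rep("0.0", 16), collapse = " "))
  p <- read_dipwm(txt)
  expect_s3_class(p, "dipwm")
  expect_equal(p$name, "X")
  expect_equal(p$m, 2L)
  expect_true(all(p$scores == 0))

  # five data rows, no header: a length-6 motif, default name
  rows <- replicate(5, paste(round(rnorm(16), 3), collapse = "\t"))
  p6 <- read_dipwm(c("# a comment", rows))
  expect_equal(p6$m, 6L)
  expect_equal(p6$name, "unnamed")

  expect_error(read_dipwm(paste(rep("1", 15), collapse = " ")),
               "expected 16", class = "dipwmscan_format_error")
  expect_error(read_dipwm(c(">Y", paste(c(rep("1", 15), "oops"), collapse = " "))),
               "non-numeric", class = "dipwmscan_format_error")
  expect_error(read_dipwm(c(">Y", "# nothing")),
               class = "dipwmscan_format_error")
})

test_that("write_dipwm round-trips through read_dipwm", {
  set.seed(11)
  p <- rand_dipwm(9, name = "RT_TEST")
  f <- withr::local_tempfile(fileext = ".dpwm")
  write_dipwm(p, f, digits = 10)
  q <- read_dipwm(f)
  expect_equal(q$name, "RT_TEST")
  expect_equal(q$m, p$m)
  expect_lt(max(abs(q$scores - p$scores)), 1e-8)
})

test_that("word scores are sums of dinucleotide column lookups", {
  expect_equal(score_word(zero_dipwm(5), "ACGTA"), 0)

  sc <- matrix(0, nrow = 16, ncol = 2)
  rownames(sc) <- dipwmscan:::DINUCLEOTIDES
  sc["AC", 1] <- 1.5
  sc["CG", 2] <- 2.0
  p <- dipwm(sc)
  expect_equal(score_word(p, "ACG"), 3.5)
  expect_equal(score_word(p, "ACA"), 1.5)
  expect_equal(score_word(p, c("ACG", "ACA")), c(3.5, 1.5))

  expect_error(score_word(p, "AC"), "length", class = "dipwmscan_input_error")
  expect_error(score_word(p, "ACN"), "outside ACGT",
               class = "dipwmscan_input_error")

  # random words against the direct lookup oracle
  set.seed(21)
  q <- rand_dipwm(7)
  words <- replicate(20, paste(sample(c("A", "C", "G", "T"), 7, TRUE),
                               collapse = ""))
  expect_equal(score_word(q, words),
               vapply(words, function(w) oracle_score(q, w), numeric(1),
                      USE.NAMES = FALSE))
})

test_that("score extrema match exhaustive enumeration", {
  expect_equal(score_extrema(zero_dipwm(4)),
               c(score_min = 0, score_max = 0))

  sc <- matrix(1, nrow = 16, ncol = 1)
  sc[1, 1] <- -1  # AA
  p1 <- dipwm(sc)
  expect_equal(score_extrema(p1), c(score_min = -1, score_max = 1))

  set.seed(31)
  for (m in c(3, 5, 8)) {
    p <- rand_dipwm(m)
    all_sc <- oracle_all_scores(p)
    ex <- score_extrema(p)
    expect_equal(ex[["score_min"]], min(all_sc), tolerance = 1e-12)
    expect_equal(ex[["score_max"]], max(all_sc), tolerance = 1e-12)
  }
})

test_that("LAM and LBM satisfy their recurrences and brute-force definitions", {
  expect_true(all(dipwm_lam(zero_dipwm(5)) == 0))
  expect_true(all(dipwm_lbm(zero_dipwm(5)) == 0))

  # m = 2, single column: LAM(A, 1) is the best AA/AC/AG/AT score
  sc <- matrix(-1, nrow = 16, ncol = 1)
  sc[1:4, 1] <- c(5, 1, 0, -2)   # AA=5, AC=1, AG=0, AT=-2
  p2 <- dipwm(sc)
  expect_equal(unname(dipwm_lam(p2)["A", 1]), 5)

  set.seed(41)
  m <- 6
  p <- rand_dipwm(m)
  lam <- dipwm_lam(p)
  lbm <- dipwm_lbm(p)
  all_sc <- oracle_all_scores(p)
  idx_first <- (seq_along(all_sc) - 1) %/% 4^(m - 1) + 1  # leading letter
  idx_last <- (seq_along(all_sc) - 1) %% 4 + 1            # trailing letter
  for (a in 1:4) {
    # entry(alpha, 1): best full word starting with alpha
    expect_equal(unname(lam[a, 1]), max(all_sc[idx_first == a]), tolerance = 1e-12)
    # entry(beta, m): best full word ending with beta
    expect_equal(unname(lbm[a, m]), max(all_sc[idx_last == a]), tolerance = 1e-12)
  }
  expect_true(all(lam[, m] == 0))
  expect_true(all(lbm[, 1] == 0))
  expect_equal(max(lam[, 1]), max(all_sc), tolerance = 1e-12)
  expect_equal(max(lbm[, m]), max(all_sc), tolerance = 1e-12)

  # internal recurrence at every cell
  for (i in seq_len(m - 1)) {
    for (a in 1:4) {
      best <- max(p$scores[4 * (a - 1) + 1:4, i] + lam[, i + 1])
      expect_equal(unname(lam[a, i]), unname(best), tolerance = 1e-12)
    }
  }
})

test_that("LBM equals LAM of the column-reversed, dinucleotide-transposed matrix", {
  set.seed(43)
  p <- rand_dipwm(7)
  rev_scores <- p$scores[, (p$m - 1):1, drop = FALSE]
  transp <- matrix(0, 16, p$m - 1)
  for (a in 1:4) for (b in 1:4) {
    transp[4 * (a - 1) + b, ] <- rev_scores[4 * (b - 1) + a, ]
  }
  q <- dipwm(transp)
  lam_rev <- dipwm_lam(q)
  lbm <- dipwm_lbm(p)
  expect_equal(unname(lbm), unname(lam_rev[, p$m:1]), tolerance = 1e-12)
})

test_that("every LAM entry is realized by its greedy traceback suffix", {
  set.seed(47)
  p <- rand_dipwm(6)
  lam <- dipwm_lam(p)
  for (i in seq_len(p$m)) {
    for (a in c("A", "C", "G", "T")) {
      w <- dipwmscan:::lam_traceback(p, lam, a, i)
      sc <- 0
      chars <- strsplit(w, "")[[1]]
      for (j in seq_len(p$m - i)) {
        sc <- sc + p$scores[paste0(chars[j], chars[j + 1]), i + j - 1]
      }
      expect_equal(unname(sc), unname(lam[a, i]), tolerance = 1e-12)
    }
  }
})

test_that("thresholds resolve by mode with the ratio formula", {
  sc <- matrix(0, nrow = 16, ncol = 1)
  sc[1, 1] <- -10; sc[16, 1] <- 10
  p <- dipwm(sc)
  expect_equal(resolve_threshold(p, threshold_ratio(0.8)), 6)
  expect_equal(resolve_threshold(p, threshold_ratio(1.0)), 10)
  expect_equal(resolve_threshold(p, threshold_ratio(0.0)), -10)
  expect_equal(resolve_threshold(p, threshold_score(3.25)), 3.25)
  expect_equal(resolve_threshold(p, 3.25), 3.25)

  expect_error(threshold_ratio(1.2), class = "dipwmscan_input_error")
  expect_error(threshold_ratio(-0.1), class = "dipwmscan_input_error")
  expect_error(resolve_threshold(p, threshold_pvalue(0.5)),
               "distribution", class = "dipwmscan_input_error")

  # monotone nondecreasing in the ratio
  set.seed(53)
  q <- rand_dipwm(8)
  ts <- vapply(seq(0, 1, by = 0.1),
               function(r) resolve_threshold(q, threshold_ratio(r)),
               numeric(1))
  expect_true(all(diff(ts) >= 0))
})

test_that("all word scores lie within the extrema", {
  set.seed(59)
  for (rep in 1:5) {
    p <- rand_dipwm(sample(3:9, 1))
    ex <- score_extrema(p)
    words <- replicate(50, paste(sample(c("A", "C", "G", "T"), p$m, TRUE),
                                 collapse = ""))
    sc <- score_word(p, words)
    expect_true(all(sc >= ex[["score_min"]] - 1e-9))
    expect_true(all(sc <= ex[["score_max"]] + 1e-9))
  }
})

test_that("tidy and glance summarize a matrix", {
  set.seed(61)
  p <- rand_dipwm(5, name = "TDY")
  td <- tidy(p)
  expect_equal(nrow(td), 16 * 4)
  expect_equal(td$score[td$position == 2], unname(p$scores[, 2]))
  gl <- glance(p)
  expect_equal(gl$name, "TDY")
  expect_equal(gl$m, 5L)
  expect_equal(gl$score_max, score_extrema(p)[["score_max"]])
})
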