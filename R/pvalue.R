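#' Background letter frequencies
#'
#' Order-0 i.i.d. background over A, C, G, T. The default is uniform
#' (0.25 each), the least-assumption null commonly used for PWM P-values;
#' any nonnegative frequencies summing to 1 are accepted.
#'
#' @param A,C,G,T Letter probabilities.
#' @return Named numeric vector of length 4.
#' @export
uniform_background <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
}

check_background <- function(bg) {
  if (!is.numeric(bg) || length(bg) != 4 || any(bg < 0) ||
      abs(sum(bg) - 1) > 1e-12) {
    abort("background must be 4 nonnegative A,C,G,T frequencies summing to 1",
          class = "dipwmscan_input_error")
  }
  setNames(as.numeric(bg), DNA_LETTERS)
}

#' Exact discretized score distribution of a di-PWM
#'
#' Distribution of the score of a random word of length `m` whose letters
#' are i.i.d. under the background model. Column scores are discretized to
#' integer multiples of the bin width `granularity`
#' (`round(score / granularity)` per column) and the probability mass is
#' propagated position by position over the state (last letter, binned
#' partial score) — cost O(m * sigma^2 * bins), never 4^m. The per-word
#' discretization error is at most `(m - 1) * granularity / 2`.
#'
#' @param x A [dipwm].
#' @param background Letter frequencies, see [uniform_background()].
#' @param granularity Positive bin width on the score scale (default 1e-3).
#' @return A `dipwm_score_dist` with the bin probability masses, the
#'   survival function `Pr(score >= bin)`, and the bin bounds.
#' @export
score_distribution <- function(x, background = uniform_background(),
                               granularity = 1e-3) {
  stopifnot(inherits(x, "dipwm"))
  bg <- check_background(background)
  if (!is.numeric(granularity) || length(granularity) != 1 || granularity <= 0) {
    abort("granularity must be a positive number",
          class = "dipwmscan_input_error")
  }
  K <- matrix(as.integer(round(x$scores / granularity)), nrow = 16L)
  m <- x$m

  # running bin bounds of the partial sums
  lo <- 0L; hi <- 0L
  state <- matrix(0, nrow = 4L, ncol = 1L)  # columns = bins lo..hi
  state[, 1L] <- bg
  for (i in seq_len(m - 1L)) {
    ki <- K[, i]
    nlo <- lo + min(ki); nhi <- hi + max(ki)
    new <- matrix(0, nrow = 4L, ncol = nhi - nlo + 1L)
    for (a in 1:4) {
      row <- state[a, ]
      if (all(row == 0)) next
      for (b in 1:4) {
        k <- ki[4L * (a - 1L) + b]
        off <- (lo + k) - nlo
        idx <- seq_along(row) + off
        new[b, idx] <- new[b, idx] + row * bg[b]
      }
    }
    state <- new; lo <- nlo; hi <- nhi
  }
  mass <- colSums(state)
  # outer bins can be unattainable (per-column maxima need not chain into a
  # word); trim exact-zero tails so the support bounds are attained bins
  nz <- which(mass > 0)
  mass <- mass[nz[1]:nz[length(nz)]]
  lo2 <- lo + nz[1] - 1L
  structure(
    list(granularity = granularity, bin_min = lo2,
         bin_max = lo2 + length(mass) - 1L,
         mass = mass, survival = rev(cumsum(rev(mass)))),
    class = "dipwm_score_dist"
  )
}

#' @export
print.dipwm_score_dist <- function(x, ...) {
  cat(sprintf(
    "di-PWM score distribution: %d bins of width %g, scores in [%.4g, %.4g]\n",
    length(x$mass), x$granularity, x$bin_min * x$granularity,
    x$bin_max * x$granularity))
  invisible(x)
}

#' @describeIn score_distribution One row per score bin: binned score, mass,
#'   tail probability.
#' @param ... Unused.
#' @export
tidy.dipwm_score_dist <- function(x, ...) {
  tibble(score = seq(x$bin_min, x$bin_max) * x$granularity,
         mass = x$mass, pvalue = x$survival)
}

#' @describeIn score_distribution One-row summary of the distribution.
#' @export
glance.dipwm_score_dist <- function(x, ...) {
  tibble(granularity = x$granularity, n_bins = length(x$mass),
         score_min = x$bin_min * x$granularity,
         score_max = x$bin_max * x$granularity,
         total_mass = sum(x$mass))
}

#' P-value of a score
#'
#' Tail probability `Pr(score >= s)` under the background model, evaluated
#' at the bin `floor(s / granularity)`. The conservative (floor) rounding
#' ensures a reported P-value never understates the true tail.
#'
#' @param dist A [score_distribution()].
#' @param s Numeric vector of scores.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
pvalue_of_score <- function(dist, s) {
  stopifnot(inherits(dist, "dipwm_score_dist"))
  bin <- floor(s / dist$granularity)
  idx <- pmin(pmax(bin - dist$bin_min + 1, 1), length(dist$survival) + 1)
  out <- c(dist$survival, 0)[idx]
  out[bin < dist$bin_min] <- 1
  out
}

#' Score threshold attaining a P-value
#'
#' The smallest binned score `t` with `Pr(score >= t) <= p`, so that
#' searching at `t` reports exactly the occurrences rarer than `p` (up to
#' one discretization bin). A `p` below the mass of the top bin yields a
#' threshold above the maximal score, hence zero occurrences.
#'
#' @param dist A [score_distribution()].
#' @param p Probability in `(0, 1]`.
#' @return A score (single number).
#' @export
threshold_from_pvalue <- function(dist, p) {
  stopifnot(inherits(dist, "dipwm_score_dist"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1) {
    abort("P-value must lie in (0, 1]", class = "dipwmscan_input_error")
  }
  ok <- which(dist$survival <= p)
  bin <- if (length(ok)) dist$bin_min + ok[1] - 1 else dist$bin_max + 1
  bin * dist$granularity
}

#' Annotate occurrences with P-values
#'
#' Adds a `pvalue` column: the tail probability of each occurrence's score
#' under the background model. All other columns are left unchanged.
#'
#' @param occs An occurrence tibble from [search_dipwm()].
#' @param dist A [score_distribution()] of the same matrix.
#' @return `occs` with a `pvalue` column appended.
#' @export
annotate_occurrences <- function(occs, dist) {
  stopifnot(is.data.frame(occs), inherits(dist, "dipwm_score_dist"))
  dplyr::mutate(occs, pvalue = pvalue_of_score(dist, .data$score))
}
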