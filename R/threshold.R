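#' Threshold specifications
#'
#' A search threshold can be given three ways:
#' * an **absolute score** `threshold_score(t)`, used as-is;
#' * a **score ratio** `threshold_ratio(r)` with `r` in `[0, 1]`, resolved as
#'   `theta = (score_max - score_min) * r + score_min`, the relative-threshold
#'   convention that makes cutoffs comparable across matrices;
#' * a **P-value** `threshold_pvalue(p)` with `p` in `(0, 1]`, resolved
#'   through the exact score distribution under a background model (see
#'   [score_distribution()]) as the smallest score whose tail probability is
#'   at most `p`.
#'
#' @param value The score, ratio or probability.
#' @return A `dipwm_threshold` object (mode + value).
#' @seealso [resolve_threshold()]
#' @export
threshold_score <- function(value) new_threshold("absolute", value)

#' @rdname threshold_score
#' @export
threshold_ratio <- function(value) {
  if (!is.numeric(value) || value < 0 || value > 1) {
    abort("ratio threshold must lie in [0, 1]", class = "dipwmscan_input_error")
  }
  new_threshold("ratio", value)
}

#' @rdname threshold_score
#' @export
threshold_pvalue <- function(value) {
  if (!is.numeric(value) || value <= 0 || value > 1) {
    abort("P-value threshold must lie in (0, 1]", class = "dipwmscan_input_error")
  }
  new_threshold("pvalue", value)
}

new_threshold <- function(mode, value) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  structure(list(mode = mode, value = as.numeric(value)),
            class = "dipwm_threshold")
}

#' @export
print.dipwm_threshold <- function(x, ...) {
  cat(sprintf("di-PWM threshold: %s = %g\n", x$mode, x$value))
  invisible(x)
}

# Bare numbers are accepted wherever a threshold is expected and read as
# absolute scores.
as_threshold <- function(spec) {
  if (inherits(spec, "dipwm_threshold")) return(spec)
  if (is.numeric(spec) && length(spec) == 1) return(threshold_score(spec))
  abort("threshold must be a dipwm_threshold or a single numeric score",
        class = "dipwmscan_input_error")
}

#' Resolve a threshold specification to an absolute score
#'
#' @param x A [dipwm].
#' @param spec A threshold from [threshold_score()], [threshold_ratio()] or
#'   [threshold_pvalue()]; a bare number is taken as an absolute score.
#' @param dist A [score_distribution()] of `x`; required for P-value mode.
#' @return The resolved score `t` (a single number).
#' @export
resolve_threshold <- function(x, spec, dist = NULL) {
  stopifnot(inherits(x, "dipwm"))
  spec <- as_threshold(spec)
  switch(spec$mode,
    absolute = spec$value,
    ratio = {
      ex <- score_extrema(x)
      # exact at the endpoints so ratio 1 keeps the maximal-score word(s)
      if (spec$value == 1) ex[["score_max"]]
      else if (spec$value == 0) ex[["score_min"]]
      else (ex[["score_max"]] - ex[["score_min"]]) * spec$value + ex[["score_min"]]
    },
    pvalue = {
      if (is.null(dist)) {
        abort("a score distribution is required to resolve a P-value threshold",
              class = "dipwmscan_input_error")
      }
      threshold_from_pvalue(dist, spec$value)
    }
  )
}
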