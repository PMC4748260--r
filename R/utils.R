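# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# session RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Percentage with half-up rounding
#'
#' Computes `100 * count / total` rounded half-up to a fixed number of decimal
#' places, the convention used in the length-bin structure summaries (e.g.
#' 353/602 -> 58.64, 2/22 -> 9.09). Returns 0 when `total` is 0.
#'
#' @param count Numerator count (vectorised).
#' @param total Denominator count.
#' @param digits Decimal places to keep (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' percentage(353, 602)
#' percentage(2, 22)
#' @export
percentage <- function(count, total, digits = 2) {
  p <- ifelse(total == 0, 0, 100 * count / total)
  round_half_up(p, digits)
}

# base::round() rounds half to even; table percentages use half-up
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
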