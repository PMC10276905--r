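# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
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
  force(code)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves going up (0.05 -> 0.1), the
#' convention used for printed percentages in clinical baseline tables,
#' rather than R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format "x.x (n)" percentage cells and "m [q1, q3]" median cells.
fmt_pct <- function(freq, n, digits = 1) {
  sprintf("%.*f (%s)", digits, round_half_up(100 * freq / n, digits),
          format(freq, big.mark = ",", trim = TRUE))
}

fmt_median_iqr <- function(x, digits = 2) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f [%.*f, %.*f]", digits, q[2], digits, q[1], digits, q[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
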