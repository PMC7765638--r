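# Internal helpers shared across modules.

# Days per year used everywhere dates are converted to years.
DAYS_PER_YEAR <- 365.25

#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical tables conventionally round
#' half away from zero (so 2.5 -> 3, 49.5 -> 50). Used by the integer-percent
#' formatter.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as an integer percent
#'
#' @param p proportion(s) in `[0, 1]` (NA allowed).
#' @return integer percent(s); NA preserved.
#' @export
pct_int <- function(p) {
  as.integer(round_half_up(100 * p))
}

#' Format a proportion as a two-significant-figure percent
#'
#' @param p proportion(s) in `[0, 1]` (NA allowed).
#' @return percent(s) rounded to 2 significant figures.
#' @export
pct_2sf <- function(p) {
  signif(100 * p, 2)
}

# Derive a reproducible sub-seed for a named RNG stream from a root seed.
# Keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Run an expression under a named RNG substream without disturbing the
# caller's RNG state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stream))
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
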