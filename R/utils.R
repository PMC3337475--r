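#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so that generator calls never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' `base::round()` rounds half to even; printed percentages in reports use
#' conventional half-up rounding (129/155 -> 83.2).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Express a ratio as a printed percentage
#'
#' Computes `100 * num / den` rounded half-up to `digits` decimals, the
#' convention used for all reported sensitivities, positive predictive
#' values and coverage fractions.
#'
#' @param num Numerator count.
#' @param den Denominator count; must be positive.
#' @param digits Decimal places to keep (default 1).
#' @return A single number on the percent scale.
#' @export
#' @examples
#' fraction_percent(129, 155)  # 83.2
fraction_percent <- function(num, den, digits = 1) {
  stopifnot(is.numeric(num), is.numeric(den), den > 0)
  round_half_up(100 * num / den, digits)
}

# internal input checks ------------------------------------------------------

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("`%s` must be a non-empty string", what), call. = FALSE)
  }
  invisible(x)
}

assert_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", what), call. = FALSE)
  }
  invisible(x)
}
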