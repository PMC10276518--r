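# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; diagnostic tables in this field
#' conventionally display percentages rounded half-up to one decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(94.55, 1)  # 94.6, where round() would give 94.5
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' Format a fraction as a display percentage
#'
#' @param x fraction in \[0,1\].
#' @param digits decimals shown (default 1, the usual table convention).
#' @return numeric percentage rounded half-up.
#' @export
as_percent <- function(x, digits = 1) round_half_up(100 * x, digits)

# Validate a scalar probability-like argument; `name` appears in the error.
check_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("'%s' must be a single number in %s", name,
                 if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == floor(x)
  if (!ok) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
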