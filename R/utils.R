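# Internal helpers shared across modules.

#' Round half-up
#'
#' Base `round()` uses banker's rounding; clinical tables round halves away
#' from zero. Used for every percentage printed in summary tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("osteoscreen_validation_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_validation(name, " must be a single finite number")
  if (strict_lower && x <= lower)
    stop_validation(name, " must be > ", lower)
  if (!strict_lower && x < lower)
    stop_validation(name, " must be >= ", lower)
  if (x > upper)
    stop_validation(name, " must be <= ", upper)
  invisible(x)
}

assert_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 2 || any(!is.finite(p)))
    stop_validation(name, " must be a finite (x, y) pair")
  invisible(p)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))
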