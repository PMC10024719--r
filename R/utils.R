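# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral of a uniformly or non-uniformly sampled signal
#' @param t sample times (s) or, if `y` is missing, `t` is taken as `y`
#'   sampled at unit spacing.
#' @param y sample values.
#' @return scalar integral.
#' @keywords internal
#' @noRd
trapz <- function(t, y) {
  if (missing(y)) {
    y <- t
    t <- seq_along(y)
  }
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

# Cumulative trapezoid, same length as input, starting at 0.
cumtrapz <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Signal a classed error so callers can condition on failure modes
# (e.g. class "codseg_no_start") rather than matching message strings.
codseg_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "codseg_error")))
}

stopifnot_scalar_num <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0))
    codseg_stop("codseg_invalid_argument",
                "`%s` must be a finite %s numeric scalar", name,
                if (positive) "positive" else "")
  invisible(x)
}
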