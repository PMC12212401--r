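`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

# Cumulative trapezoid with a virtual (0, 0) anchor point; t must be
# increasing and nonnegative.
cumtrapz0 <- function(t, y) {
  tt <- c(0, t)
  yy <- c(0, y)
  cumsum(c(0, diff(tt) * (yy[-1] + yy[-length(yy)]) / 2))[-1]
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# 18F physical half-life in minutes.
HALF_LIFE_18F <- 109.77
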