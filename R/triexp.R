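#' Triexponential curve parameters
#'
#' Sum of three decaying exponentials, zero before \code{onset}:
#' \deqn{C(t) = \sum_i A_i e^{-L_i (t - onset)}, \quad t \ge onset.}
#' Used to model the tail of a blood input function and to project it beyond
#' the measured range.
#'
#' @param A amplitudes (kBq/mL), length 3, nonnegative.
#' @param L decay rates (1/min), length 3, all > 0.
#' @param onset onset time (minutes); the curve is 0 before it.
#' @return An object of class \code{triexp_params}.
#' @export
triexp_params <- function(A, L, onset = 0) {
  A <- as.numeric(A); L <- as.numeric(L)
  if (length(A) != 3L || length(L) != 3L)
    stop("'A' and 'L' must have length 3")
  if (any(!is.finite(A)) || any(A < 0)) stop("amplitudes must be >= 0")
  if (any(!is.finite(L)) || any(L <= 0)) stop("rates must be > 0")
  stopifnot_scalar(onset, "onset")
  structure(list(A = A, L = L, onset = onset), class = "triexp_params")
}

#' Evaluate a triexponential curve
#'
#' @param params a \code{triexp_params}.
#' @param times times in minutes.
#' @return Values (kBq/mL); 0 before the onset time.  The model extrapolates
#'   smoothly beyond any fitted range.
#' @export
evaluate_triexp <- function(params, times) {
  tt <- as.numeric(times) - params$onset
  out <- numeric(length(tt))
  ok <- tt >= 0
  if (any(ok))
    out[ok] <- colSums(params$A * exp(-outer(params$L, tt[ok])))
  out
}

#' Fit a triexponential to the tail of an input-function curve
#'
#' Least-squares fit of \eqn{A_1 e^{-L_1 (t-t_0)} + A_2 e^{-L_2 (t-t_0)} +
#' A_3 e^{-L_3 (t-t_0)}} to the frames whose mid-time is at or after
#' \code{fit_start} (post-peak).  The rates are searched by
#' Levenberg-Marquardt from a fixed set of log-spaced multistart
#' initializations; at each start the amplitudes are initialized by
#' nonnegative linear least squares.  The best start wins.  An all-zero
#' curve yields a zero-amplitude fit with objective 0.
#'
#' @param input_curve a \code{tac}; its decay-correction state is recorded
#'   in the result but not altered.
#' @param fit_start first frame mid-time (minutes) included in the fit;
#'   frames before it (the bolus rise and peak) are ignored.  At least 7
#'   post-peak frames are required.
#' @param n_starts number of multistart rate initializations.
#' @param weights optional per-frame weights for the used frames; default
#'   frame durations.
#' @return An object of class \code{triexp_fit} with \code{params}
#'   (\code{triexp_params}, onset at \code{fit_start}), \code{objective},
#'   \code{converged}, \code{n_iter}, \code{method_tag}.
#' @export
fit_triexp <- function(input_curve, fit_start, n_starts = 8L,
                       weights = NULL) {
  if (!inherits(input_curve, "tac")) stop("'input_curve' must be a tac")
  tm <- frame_mid(input_curve$schedule)
  use <- tm >= fit_start
  if (sum(use) < 7L)
    stop("at least 7 post-peak frames are required for a triexponential fit")
  t0 <- fit_start
  tt <- tm[use] - t0
  y <- input_curve$values[use]
  w <- weights %||% input_curve$schedule$duration[use]
  sw <- sqrt(w)
  # frame values are averages, not point samples: the model average of
  # exp(-L (t - t0)) over [a, b] is (exp(-L(a-t0)) - exp(-L(b-t0)))/(L(b-a)),
  # the curve being 0 before the onset t0
  fa <- pmax(input_curve$schedule$start[use], t0) - t0
  fb <- frame_end(input_curve$schedule)[use] - t0
  fd <- input_curve$schedule$duration[use]
  basis_avg <- function(L)   # length-3 rates -> (frames x 3) design matrix
    vapply(L, function(l) (exp(-l * fa) - exp(-l * fb)) / (l * fd),
           numeric(length(fa)))

  if (all(y == 0)) {
    pars <- triexp_params(c(0, 0, 0), c(0.5, 0.05, 0.005), onset = t0)
    return(structure(list(params = pars, objective = 0, converged = TRUE,
                          n_iter = 0L, method_tag = "triexp-multistart",
                          fit_start = fit_start, used = use,
                          input_curve = input_curve),
                     class = "triexp_fit"))
  }

  # multistart over log-spaced rate triples spanning fast..slow clearance
  span <- exp(seq(log(0.8), log(2.2), length.out = n_starts))
  base_L <- c(0.5, 0.05, 0.005)
  best <- NULL
  for (s in span) {
    L0 <- base_L * s
    X <- basis_avg(L0)
    A0 <- tryCatch(pracma::lsqnonneg(X * sw, y * sw)$x,
                   error = function(e) rep(max(y) / 3, 3))
    p0 <- c(A0, log(L0))
    fit <- tryCatch(minpack.lm::nls.lm(
      par = p0,
      fn = function(p) {
        v <- as.numeric(basis_avg(exp(p[4:6])) %*% pmax(p[1:3], 0))
        sw * (y - v)
      },
      lower = c(0, 0, 0, rep(log(1e-5), 3)),
      upper = c(rep(Inf, 3), rep(log(20), 3)),
      control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("triexponential fit failed at every start")
  o <- order(exp(best$par[4:6]), decreasing = TRUE)
  pars <- triexp_params(pmax(best$par[1:3], 0)[o], exp(best$par[4:6])[o],
                        onset = t0)
  structure(list(params = pars, objective = best$deviance,
                 converged = best$info %in% 1:3, n_iter = best$niter,
                 method_tag = "triexp-multistart", fit_start = fit_start,
                 used = use, input_curve = input_curve),
            class = "triexp_fit")
}

#' @export
coef.triexp_fit <- function(object, ...)
  c(A1 = object$params$A[1], A2 = object$params$A[2],
    A3 = object$params$A[3], L1 = object$params$L[1],
    L2 = object$params$L[2], L3 = object$params$L[3],
    onset = object$params$onset)

#' @export
#' @param newtimes times (minutes) at which to evaluate the fitted model.
#' @rdname fit_triexp
predict.triexp_fit <- function(object, newtimes, ...)
  evaluate_triexp(object$params, newtimes)

#' @export
print.triexp_fit <- function(x, ...) {
  cat(sprintf("Triexponential tail fit (from %.1f min, %d frames)\n",
              x$fit_start, sum(x$used)))
  print(round(coef(x), 5))
  cat(sprintf("objective: %.5g, converged: %s\n", x$objective, x$converged))
  invisible(x)
}
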