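#' Compartment-model parameter sets
#'
#' Micro-parameters of the 1-tissue compartment model (reversible tracer) and
#' the 2-tissue irreversible model (k4 fixed at 0).  Units: K1 in
#' mL/min/cm^3, k2 and k3 in 1/min, vB a unitless blood fraction in [0, 1],
#' delay in minutes (a rightward shift of the input function).
#'
#' @param K1,k2,k3 rate constants; \code{K1 >= 0}, \code{k2 > 0},
#'   \code{k3 >= 0}.
#' @param vB blood volume fraction in [0, 1].
#' @param delay input delay in minutes.
#' @return A classed parameter list.
#' @seealso [macro_params()]
#' @export
onetcm_params <- function(K1, k2, vB = 0, delay = 0) {
  stopifnot_scalar(K1, "K1"); stopifnot_scalar(k2, "k2", positive = TRUE)
  stopifnot_scalar(vB, "vB"); stopifnot_scalar(delay, "delay")
  if (K1 < 0) stop("K1 must be >= 0")
  if (vB < 0 || vB > 1) stop("vB must lie in [0, 1]")
  structure(list(K1 = K1, k2 = k2, vB = vB, delay = delay),
            class = c("onetcm_params", "tcm_params"))
}

#' @rdname onetcm_params
#' @export
twotcm_params <- function(K1, k2, k3, vB = 0, delay = 0) {
  stopifnot_scalar(K1, "K1"); stopifnot_scalar(k2, "k2")
  stopifnot_scalar(k3, "k3"); stopifnot_scalar(vB, "vB")
  stopifnot_scalar(delay, "delay")
  if (K1 < 0 || k3 < 0) stop("K1 and k3 must be >= 0")
  if (k2 <= 0 || k2 + k3 <= 0) stop("k2 must be > 0")
  if (vB < 0 || vB > 1) stop("vB must lie in [0, 1]")
  structure(list(K1 = K1, k2 = k2, k3 = k3, vB = vB, delay = delay),
            class = c("twotcm_params", "tcm_params"))
}

#' Macro-parameters: volume of distribution and net influx rate
#'
#' For the 1-tissue model the volume of distribution is \code{V_T = K1/k2}
#' (mL/cm^3); for the 2-tissue irreversible model the net influx rate is
#' \code{K_i = K1*k3/(k2+k3)} (mL/min/cm^3).
#'
#' @param params a \code{onetcm_params} or \code{twotcm_params} object.
#' @return Named list with \code{V_T} or \code{K_i}.
#' @examples
#' macro_params(onetcm_params(K1 = 0.12, k2 = 0.2))      # V_T = 0.6
#' macro_params(twotcm_params(0.1, 0.1, 0.02))           # K_i = 1/60
#' @export
macro_params <- function(params) {
  if (inherits(params, "onetcm_params")) {
    if (params$k2 == 0) stop("k2 must be > 0 for V_T")
    list(V_T = params$K1 / params$k2)
  } else if (inherits(params, "twotcm_params")) {
    if (params$k2 + params$k3 == 0) stop("k2 + k3 must be > 0 for K_i")
    list(K_i = params$K1 * params$k3 / (params$k2 + params$k3))
  } else stop("unknown parameter class")
}

# Exact convolution of a piecewise-linear input (values cp on a uniform grid
# of step dt) with exp(-k t).  Returns the convolution integral
# F(t_j) = int_0^{t_j} exp(-k (t_j - s)) cp(s) ds at the grid points.
# For k = 0 this is the cumulative trapezoid.  The per-segment integral is
# closed-form, so the only approximation is the linear interpolation of the
# input between grid points; the linear recurrence is evaluated by
# stats::filter (C speed).
exp_conv_grid <- function(cp, dt, k) {
  n <- length(cp)
  if (n < 2L) return(numeric(n))
  a <- cp[-n]
  b <- (cp[-1L] - cp[-n]) / dt
  if (k <= 0) {
    seg <- a * dt + b * dt^2 / 2
    return(c(0, cumsum(seg)))
  }
  E <- exp(-k * dt)
  g <- a * (1 - E) / k + b * (dt / k - (1 - E) / k^2)
  c(0, as.numeric(stats::filter(g, E, method = "recursive")))
}

# Coerce an input-function argument (function of time or tac) to a
# vectorized continuous function of study-clock time, zero where undefined
# on the left.  A tac becomes a piecewise-linear curve on nodes at the frame
# mid-times (anchored at (first frame start, 0)), whose node values are
# iteratively adjusted so that the curve's frame averages reproduce the
# measured values: frame values are integrals, not point samples, and a
# plain mid-point interpolation of short frames over a sharp bolus
# systematically distorts the peak.  Node values are kept nonnegative; the
# curve extends constantly beyond the last frame (extrapolation there is the
# caller's responsibility to avoid).
as_input_fun <- function(input) {
  if (is.function(input)) return(input)
  if (inherits(input, "tac")) {
    tm <- frame_mid(input$schedule)
    v <- input$values
    t0 <- input$schedule$start[1]
    anchored <- tm[1] > t0 + 1e-9
    nodes <- if (anchored) c(t0, tm) else tm
    nv <- if (anchored) c(0, v) else v
    fs <- input$schedule$start
    fe <- frame_end(input$schedule)
    dg <- seq(t0, max(fe),
              by = max(min(input$schedule$duration) / 4, 1 / 120))
    for (it in 1:4) {
      yg <- stats::approx(nodes, nv, xout = dg, rule = 2)$y
      Y <- c(0, cumsum(diff(dg) * (yg[-1] + yg[-length(yg)]) / 2))
      avg <- (stats::approx(dg, Y, xout = fe, rule = 2)$y -
                stats::approx(dg, Y, xout = fs, rule = 2)$y) /
        input$schedule$duration
      adj <- v - avg
      if (anchored) nv[-1] <- pmax(nv[-1] + adj, 0)
      else nv <- pmax(nv + adj, 0)
    }
    return(function(t) {
      out <- stats::approx(nodes, nv, xout = t, rule = 2)$y
      out[t < nodes[1]] <- 0
      out
    })
  }
  stop("'input' must be a function of time or a tac")
}

# Shared grid machinery for the model evaluators: sample the (possibly
# delayed) input on a uniform grid from 0 to tmax and return grid,
# input-on-grid and a linear interpolator factory.
input_on_grid <- function(input, tmax, delay, dt) {
  f <- as_input_fun(input)
  n <- max(2L, ceiling(tmax / dt) + 1L)
  tg <- seq(0, by = dt, length.out = n)
  s <- tg - delay
  cp <- numeric(n)
  ok <- s >= 0
  cp[ok] <- f(s[ok])
  if (any(!is.finite(cp)))
    stop("input function undefined over the required range")
  list(tg = tg, cp = cp, f = f)
}

#' Evaluate the 1-tissue compartment model
#'
#' Computes \deqn{C(t) = (1 - vB) K_1 \int_0^t e^{-k_2 (t-s)} C_p(s -
#' \mathrm{delay}) ds + vB\, C_b(t - \mathrm{delay})} with the whole-blood
#' curve used as both plasma input \eqn{C_p} and blood signal \eqn{C_b}
#' (image-derived input, no plasma separation).  The convolution is exact for
#' a piecewise-linear input sampled on a fine uniform grid.
#'
#' @param params a \code{onetcm_params}.
#' @param input the input function: either a function of time (minutes,
#'   kBq/mL) or a \code{tac} (interpolated through frame mid-points).
#' @param times evaluation times in minutes, all \code{>= 0}.
#' @param dt internal grid step in minutes.
#' @return Concentrations (kBq/mL) at \code{times}.
#' @examples
#' evaluate_onetcm(onetcm_params(0.1, 0.2), function(t) rep(1, length(t)), 5)
#' @export
evaluate_onetcm <- function(params, input, times, dt = 1 / 60) {
  if (!inherits(params, "onetcm_params"))
    stop("'params' must be a onetcm_params")
  times <- as.numeric(times)
  if (any(times < 0)) stop("'times' must be >= 0")
  g <- input_on_grid(input, max(times), params$delay, dt)
  conv <- exp_conv_grid(g$cp, dt, params$k2)
  free <- (1 - params$vB) * params$K1 *
    stats::approx(g$tg, conv, xout = times, rule = 2)$y
  cb <- numeric(length(times))
  ok <- times - params$delay >= 0
  cb[ok] <- g$f(times[ok] - params$delay)
  free + params$vB * cb
}

#' Evaluate the 2-tissue irreversible compartment model
#'
#' Computes the tissue curve of the irreversibly trapping model (k4 = 0):
#' \deqn{C(t) = (1-vB) K_1 \left[\frac{k_3}{k_2+k_3}\int_0^t C_p +
#' \frac{k_2}{k_2+k_3} e^{-(k_2+k_3)t} \otimes C_p\right] + vB\, C_b,}
#' input delayed as in \code{\link{evaluate_onetcm}}.  With \code{k3 = 0} the
#' model reduces exactly to the 1-tissue model.
#'
#' @inheritParams evaluate_onetcm
#' @param params a \code{twotcm_params}.
#' @export
evaluate_twotcm_irrev <- function(params, input, times, dt = 1 / 60) {
  if (!inherits(params, "twotcm_params"))
    stop("'params' must be a twotcm_params")
  times <- as.numeric(times)
  if (any(times < 0)) stop("'times' must be >= 0")
  theta <- params$k2 + params$k3
  g <- input_on_grid(input, max(times), params$delay, dt)
  conv_th <- exp_conv_grid(g$cp, dt, theta)
  int_cp <- exp_conv_grid(g$cp, dt, 0)
  mix <- (params$k3 / theta) * int_cp + (params$k2 / theta) * conv_th
  free <- (1 - params$vB) * params$K1 *
    stats::approx(g$tg, mix, xout = times, rule = 2)$y
  cb <- numeric(length(times))
  ok <- times - params$delay >= 0
  cb[ok] <- g$f(times[ok] - params$delay)
  free + params$vB * cb
}
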