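#' Fitting options for compartment-model estimation
#'
#' @param weighting frame weighting scheme. \code{"duration-decay"} uses
#'   \code{w_i = dt_i * exp(-lambda * t_i)} (frame duration times the decay
#'   factor at the frame mid-time, an approximate inverse-variance weight for
#'   decay-corrected data); \code{"uniform"} uses \code{w_i = 1}.
#' @param half_life isotope half-life (minutes) used by the weighting scheme.
#' @param delay_grid candidate input delays (minutes).  The delay is searched
#'   exhaustively over this grid, the remaining parameters being re-estimated
#'   at every grid point; use \code{0} to fix the delay.
#' @param bounds named list of \code{c(lower, upper)} bounds for K1, k2, k3
#'   (1/min) and vB.
#' @param init named list of initial values for the Levenberg-Marquardt
#'   search.
#' @param nl_strategy how the nonlinear parameter of the separable solver is
#'   searched: \code{"grid"} (exhaustive log-spaced grid with local
#'   refinement) or \code{"lm"} (coarse grid start then 1-D refinement).
#' @param n_grid number of grid points for the separable nonlinear search.
#' @param dt internal quadrature/convolution step (minutes).
#' @return A list of class \code{fit_options}.
#' @export
fit_options <- function(weighting = c("duration-decay", "uniform"),
                        half_life = HALF_LIFE_18F,
                        delay_grid = seq(-1, 2, by = 0.1),
                        bounds = list(K1 = c(0, 5), k2 = c(1e-4, 5),
                                      k3 = c(0, 5), vB = c(0, 0.5)),
                        init = list(K1 = 0.1, k2 = 0.1, k3 = 0.01,
                                    vB = 0.05),
                        nl_strategy = c("grid", "lm"),
                        n_grid = 40L, dt = 1 / 60) {
  weighting <- match.arg(weighting)
  nl_strategy <- match.arg(nl_strategy)
  if (!length(delay_grid)) stop("'delay_grid' must be nonempty")
  for (nm in names(bounds))
    if (bounds[[nm]][1] > bounds[[nm]][2]) stop("bounds must be ordered")
  structure(list(weighting = weighting, half_life = half_life,
                 delay_grid = sort(as.numeric(delay_grid)), bounds = bounds,
                 init = init, nl_strategy = nl_strategy,
                 n_grid = as.integer(n_grid), dt = dt),
            class = "fit_options")
}

# Frame averages of a gridded continuous signal via its cumulative integral.
frame_avg_grid <- function(tg, y, schedule) {
  n <- length(tg)
  Y <- c(0, cumsum(diff(tg) * (y[-1] + y[-n]) / 2))
  Ya <- stats::approx(tg, Y, xout = schedule$start, rule = 2)$y
  Yb <- stats::approx(tg, Y, xout = frame_end(schedule), rule = 2)$y
  (Yb - Ya) / schedule$duration
}

fit_weights <- function(schedule, options, t0 = NULL) {
  t0 <- t0 %||% schedule$start[1]
  if (options$weighting == "uniform") rep(1, length(schedule$start))
  else {
    lambda <- log(2) / options$half_life
    schedule$duration * exp(-lambda * (frame_mid(schedule) - t0))
  }
}

# Weighted nonnegative least squares with an optional upper bound on the
# last coefficient (the blood fraction).  Returns coefficients and weighted
# residual sum of squares.
wnnls <- function(X, y, w, vb_max = NULL) {
  sw <- sqrt(w)
  A <- X * sw
  b <- y * sw
  co <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
  if (is.null(co)) { # degenerate columns: fall back to zero fit
    co <- rep(0, ncol(X))
  }
  k <- length(co)
  if (!is.null(vb_max) && co[k] > vb_max) {
    co2 <- tryCatch(
      pracma::lsqnonneg(A[, -k, drop = FALSE], b - vb_max * A[, k])$x,
      error = function(e) rep(0, k - 1L))
    co <- c(co2, vb_max)
  }
  r <- y - as.numeric(X %*% co)
  list(coef = co, obj = sum(w * r^2), resid = r)
}

# Per-delay context: delayed input on the internal grid plus its frame
# averages and blood frame values.
delay_context <- function(input, schedule, delay, dt) {
  tmax <- max(frame_end(schedule))
  g <- input_on_grid(input, tmax, delay, dt)
  list(tg = g$tg, cp = g$cp,
       cb_frames = frame_avg_grid(g$tg, g$cp, schedule),
       int_cp_frames = frame_avg_grid(g$tg, exp_conv_grid(g$cp, dt, 0),
                                      schedule))
}

sep_basis_1tcm <- function(ctx, schedule, k2, dt) {
  cbind(frame_avg_grid(ctx$tg, exp_conv_grid(ctx$cp, dt, k2), schedule),
        ctx$cb_frames)
}

sep_basis_2tcm <- function(ctx, schedule, theta, dt) {
  cbind(ctx$int_cp_frames,
        frame_avg_grid(ctx$tg, exp_conv_grid(ctx$cp, dt, theta), schedule),
        ctx$cb_frames)
}

# 1-D nonlinear search for the separable solver: log-spaced exhaustive grid,
# then golden-section refinement in the bracketing interval.
search_1d <- function(obj_fun, lo, hi, n_grid, refine = TRUE) {
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  vals <- vapply(grid, obj_fun, numeric(1))
  i <- which.min(vals)
  best <- list(x = grid[i], obj = vals[i], n_eval = n_grid)
  if (refine) {
    a <- grid[max(1L, i - 1L)]; b <- grid[min(n_grid, i + 1L)]
    if (b > a) {
      o <- stats::optimize(obj_fun, c(a, b), tol = 1e-6)
      if (o$objective < best$obj)
        best <- list(x = o$minimum, obj = o$objective,
                     n_eval = n_grid + 20L)
    }
  }
  best
}

#' Fit a compartment model to a time-activity curve
#'
#' Estimates the micro-parameters of the 1-tissue compartment model or the
#' 2-tissue irreversible model (k4 = 0) from a tissue TAC and a blood input
#' TAC by weighted least squares.  The blood fraction \code{vB} and the
#' input delay are estimated jointly with the rate constants: the delay is
#' searched over a discrete grid, all other parameters being re-estimated at
#' each grid point, and the best grid point wins.
#'
#' Two estimation methods are provided.  \code{method = "lm"} performs a
#' bounded Levenberg-Marquardt search over all micro-parameters at once.
#' \code{method = "separable"} uses the separable-parameter-space
#' reformulation, in which the number of linear parameters is maximized and
#' the number of nonlinear parameters minimized: for the 1-tissue model the
#' only nonlinear parameter is \code{k2} and the basis \{exp(-k2 t) (x) Cp,
#' Cb\} yields \code{K1 (1-vB)} and \code{vB} by nonnegative weighted linear
#' least squares; for the 2-tissue irreversible model the nonlinear
#' parameter is \code{theta = k2 + k3} with basis \{int Cp, exp(-theta t)
#' (x) Cp, Cb\} and linear coefficients \code{a1 = (1-vB) K1 k3/theta},
#' \code{a2 = (1-vB) K1 k2/theta}, \code{vB}, mapped back as
#' \code{K1 = (a1+a2)/(1-vB)}, \code{k3 = theta a1/(a1+a2)},
#' \code{k2 = theta a2/(a1+a2)}, \code{K_i = a1/(1-vB)}.
#' Negative linear coefficients are excluded by the nonnegativity
#' constraint (physical rate constants are nonnegative).
#'
#' @param tissue a \code{tac} with the tissue curve.
#' @param input a \code{tac} with the whole-blood input curve (used as both
#'   plasma input and blood signal).  Must share the tissue curve's
#'   decay-correction state.
#' @param model \code{"1tcm"} or \code{"2tcm-irrev"}.
#' @param method \code{"separable"} (default) or \code{"lm"}.
#' @param options a \code{\link{fit_options}} object.
#' @return An object of class \code{tcm_fit} with components \code{params}
#'   (fitted micro-parameters including delay), \code{macro} (V_T or K_i),
#'   \code{objective} (weighted residual sum of squares), \code{se}
#'   (standard errors from the local curvature), \code{converged},
#'   \code{n_iter}, \code{method_tag}, plus the data and fitted frame
#'   values.  If no delay grid point converges the result is flagged
#'   \code{converged = FALSE} rather than raising an error.
#' @seealso [macro_params()], [logan_vt()], [patlak_ki()]
#' @export
fit_tcm <- function(tissue, input,
                    model = c("1tcm", "2tcm-irrev"),
                    method = c("separable", "lm"),
                    options = fit_options()) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (!inherits(tissue, "tac") || !inherits(input, "tac"))
    stop("'tissue' and 'input' must be tac objects")
  if (tissue$decay_corrected != input$decay_corrected)
    stop("tissue and input must share one decay-correction state")
  sch <- tissue$schedule
  if (length(sch$start) != length(input$schedule$start) ||
      max(abs(sch$start - input$schedule$start)) > 1e-9)
    stop("tissue and input must share one frame schedule")
  w <- fit_weights(sch, options)
  y <- tissue$values
  dt <- options$dt
  vb_max <- options$bounds$vB[2]

  best <- NULL
  for (d in options$delay_grid) {
    ctx <- delay_context(input, sch, d, dt)
    cand <- if (method == "separable")
      fit_sep_at_delay(model, ctx, sch, y, w, options, vb_max)
    else
      fit_lm_at_delay(model, ctx, sch, y, w, options, vb_max)
    if (!is.null(cand) &&
        (is.null(best) || cand$obj < best$obj)) {
      cand$delay <- d
      best <- cand
    }
  }
  if (is.null(best))
    best <- list(params = c(K1 = NA, k2 = NA,
                            if (model != "1tcm") c(k3 = NA), vB = NA),
                 obj = Inf, converged = FALSE, n_iter = 0L, delay = NA,
                 tag = method)

  pv <- best$params
  params <- if (model == "1tcm")
    tryCatch(onetcm_params(pv[["K1"]], max(pv[["k2"]], 1e-8), pv[["vB"]],
                           best$delay), error = function(e) NULL)
  else
    tryCatch(twotcm_params(pv[["K1"]], max(pv[["k2"]], 1e-8), pv[["k3"]],
                           pv[["vB"]], best$delay), error = function(e) NULL)
  converged <- isTRUE(best$converged) && !is.null(params)

  fitted_vals <- se <- NULL
  if (!is.null(params)) {
    fitted_vals <- model_frames(model, params, input, sch, dt)
    se <- fit_se(model, params, input, sch, w, y, fitted_vals, dt)
  }
  structure(list(model = model, method_tag = best$tag,
                 params = params, macro = if (!is.null(params))
                   macro_params(params),
                 objective = best$obj, se = se,
                 converged = converged, n_iter = best$n_iter,
                 tissue = tissue, input = input, weights = w,
                 fitted_values = fitted_vals, options = options),
            class = "tcm_fit")
}

# Frame-averaged model prediction for a parameter set.
model_frames <- function(model, params, input, schedule, dt) {
  f <- if (model == "1tcm")
    function(t) evaluate_onetcm(params, input, t, dt)
  else
    function(t) evaluate_twotcm_irrev(params, input, t, dt)
  tmax <- max(frame_end(schedule))
  tg <- seq(0, tmax, by = dt)
  frame_avg_grid(tg, f(tg), schedule)
}

fit_sep_at_delay <- function(model, ctx, sch, y, w, options, vb_max) {
  dt <- options$dt
  if (model == "1tcm") {
    obj <- function(k2)
      wnnls(sep_basis_1tcm(ctx, sch, k2, dt), y, w, vb_max)$obj
    s <- search_1d(obj, max(options$bounds$k2[1], 1e-3),
                   options$bounds$k2[2], options$n_grid,
                   refine = TRUE)
    sol <- wnnls(sep_basis_1tcm(ctx, sch, s$x, dt), y, w, vb_max)
    vB <- sol$coef[2]
    K1 <- sol$coef[1] / max(1 - vB, 1e-8)
    list(params = c(K1 = K1, k2 = s$x, vB = vB), obj = sol$obj,
         converged = TRUE, n_iter = s$n_eval,
         tag = paste0("separable-", options$nl_strategy))
  } else {
    obj <- function(theta)
      wnnls(sep_basis_2tcm(ctx, sch, theta, dt), y, w, vb_max)$obj
    s <- search_1d(obj, max(options$bounds$k2[1], 1e-3),
                   options$bounds$k2[2] + options$bounds$k3[2],
                   options$n_grid, refine = TRUE)
    sol <- wnnls(sep_basis_2tcm(ctx, sch, s$x, dt), y, w, vb_max)
    a1 <- sol$coef[1]; a2 <- sol$coef[2]; vB <- sol$coef[3]
    if (a1 + a2 <= 0)
      return(list(params = c(K1 = 0, k2 = s$x, k3 = 0, vB = vB),
                  obj = sol$obj, converged = FALSE, n_iter = s$n_eval,
                  tag = paste0("separable-", options$nl_strategy)))
    K1 <- (a1 + a2) / max(1 - vB, 1e-8)
    k3 <- s$x * a1 / (a1 + a2)
    k2 <- s$x * a2 / (a1 + a2)
    list(params = c(K1 = K1, k2 = k2, k3 = k3, vB = vB), obj = sol$obj,
         converged = TRUE, n_iter = s$n_eval,
         tag = paste0("separable-", options$nl_strategy))
  }
}

fit_lm_at_delay <- function(model, ctx, sch, y, w, options, vb_max) {
  dt <- options$dt
  sw <- sqrt(w)
  pred <- function(p) {
    if (model == "1tcm") {
      conv <- exp_conv_grid(ctx$cp, dt, p[["k2"]])
      (1 - p[["vB"]]) * p[["K1"]] * frame_avg_grid(ctx$tg, conv, sch) +
        p[["vB"]] * ctx$cb_frames
    } else {
      th <- p[["k2"]] + p[["k3"]]
      conv <- exp_conv_grid(ctx$cp, dt, th)
      mix <- (p[["k3"]] / th) * ctx$int_cp_frames +
        (p[["k2"]] / th) * frame_avg_grid(ctx$tg, conv, sch)
      (1 - p[["vB"]]) * p[["K1"]] * mix + p[["vB"]] * ctx$cb_frames
    }
  }
  par0 <- unlist(options$init[c("K1", "k2", if (model != "1tcm") "k3",
                                "vB")])
  lower <- vapply(names(par0), function(n) options$bounds[[n]][1],
                  numeric(1))
  upper <- vapply(names(par0), function(n) options$bounds[[n]][2],
                  numeric(1))
  upper["vB"] <- vb_max
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) sw * (y - pred(p)),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  list(params = fit$par, obj = fit$deviance,
       converged = fit$info %in% 1:3, n_iter = fit$niter, tag = "lm")
}

# Standard errors from the local curvature of the weighted objective at the
# optimum (delay held fixed): numeric Jacobian, cov = s2 (J' W J)^-1.
fit_se <- function(model, params, input, schedule, w, y, fitted_vals, dt) {
  nm <- c("K1", "k2", if (model != "1tcm") "k3", "vB")
  p0 <- unlist(params[nm])
  J <- matrix(0, length(y), length(p0), dimnames = list(NULL, nm))
  for (j in seq_along(p0)) {
    h <- max(1e-5, abs(p0[j]) * 1e-4)
    pp <- pm <- params
    pp[[nm[j]]] <- p0[j] + h
    pm[[nm[j]]] <- max(p0[j] - h, if (nm[j] == "k2") 1e-8 else 0)
    fp <- model_frames(model, pp, input, schedule, dt)
    fm <- model_frames(model, pm, input, schedule, dt)
    J[, j] <- (fp - fm) / (p0[j] + h - pm[[nm[j]]])
  }
  r <- y - fitted_vals
  dof <- max(length(y) - length(p0), 1L)
  s2 <- sum(w * r^2) / dof
  H <- crossprod(J * sqrt(w))
  se <- rep(NA_real_, length(p0)); names(se) <- nm
  cv <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv) * s2
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  se
}

#' @export
coef.tcm_fit <- function(object, ...) {
  if (is.null(object$params)) return(NULL)
  p <- object$params
  out <- unlist(p[setdiff(names(p), "delay")])
  c(out, delay = p$delay, unlist(object$macro))
}

#' @export
fitted.tcm_fit <- function(object, ...) object$fitted_values

#' @export
residuals.tcm_fit <- function(object, ...)
  object$tissue$values - object$fitted_values

#' @export
#' @param newtimes optional times (minutes) at which to evaluate the fitted
#'   continuous model; omitted, the frame-averaged fitted values are
#'   returned.
#' @rdname fit_tcm
predict.tcm_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(object$params)) stop("fit did not produce valid parameters")
  if (is.null(newtimes)) return(object$fitted_values)
  if (object$model == "1tcm")
    evaluate_onetcm(object$params, object$input, newtimes,
                    object$options$dt)
  else
    evaluate_twotcm_irrev(object$params, object$input, newtimes,
                          object$options$dt)
}

#' @export
print.tcm_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s) of '%s'\n",
              toupper(x$model), x$method_tag, x$tissue$region))
  if (!is.null(x$params)) {
    print(round(coef(x), 5))
    cat(sprintf("objective (wRSS): %.5g, converged: %s, iterations: %d\n",
                x$objective, x$converged, x$n_iter))
  } else cat("fit failed: no valid parameters\n")
  invisible(x)
}

#' @export
summary.tcm_fit <- function(object, ...) {
  est <- coef(object)
  nm <- names(object$se)
  tab <- cbind(Estimate = est[nm], `Std. Error` = object$se)
  structure(list(fit = object, table = tab, macro = object$macro),
            class = "summary.tcm_fit")
}

#' @export
print.summary.tcm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter table:\n")
  print(round(x$table, 5))
  invisible(x)
}

#' @export
plot.tcm_fit <- function(x, ...) {
  tm <- frame_mid(x$tissue$schedule)
  graphics::plot(tm, x$tissue$values, pch = 16,
                 xlab = "time (min)", ylab = "activity (kBq/mL)",
                 main = sprintf("%s fit: %s", toupper(x$model),
                                x$tissue$region), ...)
  if (!is.null(x$fitted_values))
    graphics::lines(tm, x$fitted_values, col = 2, lwd = 2)
  graphics::legend("topright", c("measured", "fitted"),
                   pch = c(16, NA), lty = c(NA, 1), col = c(1, 2))
  invisible(x)
}
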