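graphical_common <- function(tissue, input, t_star, kind) {
  if (!inherits(tissue, "tac") || !inherits(input, "tac"))
    stop("'tissue' and 'input' must be tac objects")
  if (!isTRUE(tissue$decay_corrected) || !isTRUE(input$decay_corrected) ||
      abs(tissue$decay_reference - input$decay_reference) > 1e-6)
    stop("both curves must be decay-corrected to the same reference")
  tm <- frame_mid(tissue$schedule)
  ct <- tissue$values
  cp <- input$values
  int_ct <- cumtrapz0(tm, ct)
  int_cp <- cumtrapz0(tm, cp)
  use <- tm >= t_star
  if (sum(use) < 3L)
    stop("fewer than 3 usable frames at or after t_star")
  if (kind == "VT" && any(ct[use] <= 0))
    stop("tissue values after t_star must be > 0 for a Logan plot")
  if (kind == "Ki" && any(cp[use] <= 0))
    stop("input values after t_star must be > 0 for a Patlak plot")
  if (kind == "VT") {
    x <- int_cp / ct
    yv <- int_ct / ct
  } else {
    x <- int_cp / cp
    yv <- ct / cp
  }
  fit <- stats::lsfit(x[use], yv[use])
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((yv[use] - mean(yv[use]))^2)
  structure(list(slope = slope, intercept = intercept, t_star = t_star,
                 n_points_used = sum(use),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 estimate_kind = kind, x = x, y = yv, used = use,
                 mid_times = tm, region = tissue$region),
            class = "graphical_fit")
}

#' Logan graphical estimate of the volume of distribution
#'
#' Ordinary least squares of \eqn{y(t) = \int_0^t C_T / C_T(t)} on
#' \eqn{x(t) = \int_0^t C_p / C_T(t)} over frames with mid-time at or after
#' \code{t_star}; the asymptotic slope estimates \eqn{V_T} for a reversible
#' tracer.  Cumulative integrals use the trapezoid rule over frame mid-times
#' with a virtual (0, 0) anchor.
#'
#' @param tissue,input decay-corrected \code{tac} objects sharing one
#'   reference time; time zero is the injection.
#' @param t_star start of the linear segment, minutes (default 15).
#' @return A \code{graphical_fit}: slope (the estimate), intercept,
#'   \code{t_star}, number of points used, and \code{r_squared}.
#' @seealso [patlak_ki()], [select_tstar()]
#' @export
logan_vt <- function(tissue, input, t_star = 15)
  graphical_common(tissue, input, t_star, "VT")

#' Patlak graphical estimate of the net influx rate
#'
#' Ordinary least squares of \eqn{y(t) = C_T(t)/C_p(t)} on normalized time
#' \eqn{x(t) = \int_0^t C_p / C_p(t)} over frames with mid-time at or after
#' \code{t_star}; the slope estimates \eqn{K_i} for an irreversibly trapped
#' tracer.
#'
#' @inheritParams logan_vt
#' @param t_star start of the linear segment, minutes (default 20).
#' @export
patlak_ki <- function(tissue, input, t_star = 20)
  graphical_common(tissue, input, t_star, "Ki")

#' Select the start of the linear segment of a graphical plot
#'
#' Returns the smallest frame mid-time such that, when the regression is
#' restricted to that point onward, every used point deviates from the
#' regression line by less than \code{max_rel_error} (relative to the line).
#' If the criterion is never met the latest feasible start (leaving 3
#' points) is returned with a warning.
#'
#' @inheritParams logan_vt
#' @param estimator \code{"logan"} or \code{"patlak"}.
#' @param max_rel_error maximum tolerated relative deviation (default 0.10).
#' @return t_star in minutes.
#' @export
select_tstar <- function(tissue, input, estimator = c("logan", "patlak"),
                         max_rel_error = 0.10) {
  estimator <- match.arg(estimator)
  fun <- if (estimator == "logan") logan_vt else patlak_ki
  tm <- frame_mid(tissue$schedule)
  cand <- tm[seq_len(length(tm) - 2L)]
  for (ts in cand) {
    g <- tryCatch(fun(tissue, input, ts), error = function(e) NULL)
    if (is.null(g)) next
    pred <- g$intercept + g$slope * g$x[g$used]
    dev <- abs(g$y[g$used] - pred) / pmax(abs(pred), 1e-12)
    if (all(dev < max_rel_error)) return(ts)
  }
  warning("linearity criterion never met; returning latest feasible t_star")
  cand[length(cand)]
}

#' @export
coef.graphical_fit <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)

#' @export
print.graphical_fit <- function(x, ...) {
  lbl <- if (x$estimate_kind == "VT") "Logan V_T (mL/cm^3)"
         else "Patlak K_i (mL/min/cm^3)"
  cat(sprintf("%s plot, '%s': %s = %.5g\n",
              if (x$estimate_kind == "VT") "Logan" else "Patlak",
              x$region, lbl, x$slope))
  cat(sprintf("t* = %.1f min, %d points, intercept %.4g, r^2 = %.4f\n",
              x$t_star, x$n_points_used, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
plot.graphical_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = ifelse(x$used, 16, 1),
                 xlab = "normalized x", ylab = "normalized y",
                 main = sprintf("%s plot (%s)",
                                if (x$estimate_kind == "VT") "Logan"
                                else "Patlak", x$region), ...)
  graphics::abline(x$intercept, x$slope, col = 2, lwd = 2)
  invisible(x)
}

#' Export the points of a graphical plot
#'
#' @param fit a \code{graphical_fit}.
#' @param file optional CSV path; when given, the table is written there.
#' @return Data frame with mid-time, x, y and a used/unused flag per point.
#' @export
graphical_plot_data <- function(fit, file = NULL) {
  df <- data.frame(mid_time_min = fit$mid_times, x = fit$x, y = fit$y,
                   used = fit$used)
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
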