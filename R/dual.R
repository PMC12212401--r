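#' Assemble a dual-tracer study from measured curves
#'
#' @param injections list of two \code{\link{injection_event}}s ordered by
#'   time (the second strictly after the first).
#' @param input_curve the image-derived blood input \code{tac}, spanning
#'   both segments, decay-corrected to the first injection.
#' @param tissue_curves named list of tissue \code{tac}s on the same
#'   schedule.
#' @param body_weight kg.
#' @return An object of class \code{dual_tracer_study}.
#' @export
dual_tracer_study <- function(injections, input_curve, tissue_curves,
                              body_weight) {
  if (length(injections) != 2L ||
      !all(vapply(injections, inherits, TRUE, "injection_event")))
    stop("'injections' must be a list of two injection_event objects")
  if (injections[[2]]$time_min <= injections[[1]]$time_min)
    stop("second injection must be strictly after the first")
  stopifnot_scalar(body_weight, "body_weight", positive = TRUE)
  sch <- input_curve$schedule
  for (tc in tissue_curves)
    if (max(abs(tc$schedule$start - sch$start)) > 1e-9)
      stop("all curves must share one frame schedule")
  t2 <- injections[[2]]$time_min
  tm <- frame_mid(sch)
  if (!any(tm < t2) || !any(tm >= t2))
    stop("schedule must span both segments")
  structure(list(injections = injections, input_curve = input_curve,
                 tissue_curves = tissue_curves, body_weight = body_weight),
            class = c("dual_tracer_study", "tracer_study"))
}

# Take a subset of frames of a tac, preserving decay state.
subset_tac <- function(curve, idx) {
  tac(frame_schedule(curve$schedule$start[idx],
                     curve$schedule$duration[idx]),
      curve$values[idx], region = curve$region,
      decay_corrected = curve$decay_corrected,
      decay_reference = curve$decay_reference)
}

# Shift the time axis of a tac (e.g. re-zero to the second injection).
shift_tac <- function(curve, by) {
  tac(frame_schedule(curve$schedule$start + by, curve$schedule$duration),
      curve$values, region = curve$region,
      decay_corrected = curve$decay_corrected,
      decay_reference = if (curve$decay_corrected)
        curve$decay_reference + by)
}

# Frame indices of the two segments; straddling frames are dropped with a
# warning (the generator guarantees a boundary at t2, so none arise there).
segment_indices <- function(schedule, t2) {
  tm <- frame_mid(schedule)
  fe <- frame_end(schedule)
  straddle <- schedule$start < t2 - 1e-9 & fe > t2 + 1e-9
  if (any(straddle))
    warning(sprintf("%d frame(s) straddle the second injection; dropped",
                    sum(straddle)))
  list(first = which(tm < t2 & !straddle),
       second = which(tm >= t2 & !straddle))
}

#' Split a dual-tracer study at the second injection
#'
#' Frames are assigned by mid-time relative to the second injection time;
#' a frame whose boundary falls exactly on the injection time belongs to
#' the second segment (half-open convention).  Frames straddling the
#' injection are dropped with a warning.
#'
#' @param study a \code{dual_tracer_study}.
#' @return List with elements \code{first} and \code{second}, each holding
#'   \code{input} and \code{tissues} curves, plus \code{t2}.
#' @export
segment_study <- function(study) {
  if (!inherits(study, "dual_tracer_study"))
    stop("'study' must be a dual_tracer_study")
  t2 <- study$injections[[2]]$time_min
  idx <- segment_indices(study$input_curve$schedule, t2)
  if (!length(idx$first) || !length(idx$second))
    stop("a segment is empty: second injection outside the scan")
  seg <- function(i)
    list(input = subset_tac(study$input_curve, i),
         tissues = lapply(study$tissue_curves, subset_tac, idx = i))
  list(first = seg(idx$first), second = seg(idx$second), t2 = t2,
       indices = idx)
}

#' Correct the input function for residual first-tracer signal
#'
#' Implements the projection-subtraction correction: (1) remove decay
#' correction (reference = first injection); (2) fit a triexponential to
#' the post-peak first-segment input; (3) extrapolate it over the second
#' segment; (4) subtract it from the measured input; (5) reapply decay
#' correction with the second injection as reference.  Negative corrected
#' values are clipped to 0 and counted.
#'
#' @param study a \code{dual_tracer_study} whose curves are decay-corrected
#'   to the first injection.
#' @param triexp_fit_start start of the triexponential fit window, minutes
#'   after the first injection (post-peak; default 5).
#' @return List of class \code{input_correction}: \code{corrected_input}
#'   (second-segment \code{tac}, decay-corrected to the second injection),
#'   \code{projection} (decay-uncorrected projected first-tracer input over
#'   the second segment), \code{triexp_fit}, \code{n_clipped},
#'   \code{input_fun_first} and \code{input_fun_second} (continuous
#'   decay-uncorrected per-tracer input models for downstream fitting).
#' @export
correct_input_function <- function(study, triexp_fit_start = 5) {
  if (!inherits(study, "dual_tracer_study"))
    stop("'study' must be a dual_tracer_study")
  inp <- study$input_curve
  if (!isTRUE(inp$decay_corrected))
    stop("input curve must be decay-corrected on entry")
  inj1 <- study$injections[[1]]; inj2 <- study$injections[[2]]
  t2 <- inj2$time_min
  uncorr <- decay_correct(inp, inj1$half_life_min, inp$decay_reference,
                          "remove")
  idx <- segment_indices(inp$schedule, t2)
  first <- subset_tac(uncorr, idx$first)
  second <- subset_tac(uncorr, idx$second)

  fit <- fit_triexp(first, fit_start = inj1$time_min + triexp_fit_start)
  proj_fun <- function(t) evaluate_triexp(fit$params, t)
  projection <- frame_average(proj_fun, second$schedule, region = "blood")

  corr_vals <- second$values - projection$values
  n_clipped <- sum(corr_vals < 0)
  corr_vals <- pmax(corr_vals, 0)
  corrected_unc <- tac(second$schedule, corr_vals, region = "blood")
  corrected <- decay_correct(corrected_unc, inj2$half_life_min, t2, "apply")

  # continuous per-tracer input models in the decay-uncorrected domain:
  # first tracer = measured while measured, triexponential beyond; second
  # tracer = measured minus projection, zero before its injection.
  f_meas1 <- as_input_fun(first)
  t_break <- max(frame_mid(first$schedule))
  input_fun_first <- function(t) {
    out <- numeric(length(t))
    a <- t <= t_break
    out[a] <- f_meas1(t[a])
    out[!a] <- proj_fun(t[!a])
    out
  }
  f_corr2 <- as_input_fun(corrected_unc)
  input_fun_second <- function(t) {
    out <- numeric(length(t))
    a <- t >= t2
    out[a] <- f_corr2(t[a])
    out
  }
  structure(list(corrected_input = corrected, projection = projection,
                 triexp_fit = fit, n_clipped = n_clipped,
                 input_fun_first = input_fun_first,
                 input_fun_second = input_fun_second,
                 uncorrected_input = uncorr, indices = idx, t2 = t2),
            class = "input_correction")
}

#' Subtract projected first-tracer signal from the tissue curves
#'
#' For each region with an available first-tracer 1-tissue fit (obtained on
#' the decay-uncorrected first-segment data), the fitted forward model is
#' driven by the projected decay-uncorrected first-tracer input over the
#' whole study, its second-segment frame averages are subtracted from the
#' measured curves, negatives are clipped to 0 (and counted), and decay
#' correction is reapplied with the second injection as reference.
#'
#' @param study a \code{dual_tracer_study} (curves decay-corrected to the
#'   first injection).
#' @param first_tracer_fits named list of \code{tcm_fit} objects (1TCM,
#'   decay-uncorrected first-segment fits), one per region; regions without
#'   a fit are skipped with a warning.
#' @param correction an \code{input_correction} from
#'   \code{\link{correct_input_function}}.
#' @return List of class \code{tissue_correction}: \code{corrected_tissues}
#'   (decay-corrected to the second injection), \code{projected_tissues}
#'   (decay-uncorrected residual curves), \code{n_clipped} per region.
#' @export
subtract_tissue_residual <- function(study, first_tracer_fits, correction) {
  inj1 <- study$injections[[1]]; inj2 <- study$injections[[2]]
  t2 <- correction$t2
  idx <- correction$indices
  corrected <- projected <- list()
  n_clipped <- integer(0)
  dt <- 1 / 60
  sch2 <- frame_schedule(study$input_curve$schedule$start[idx$second],
                         study$input_curve$schedule$duration[idx$second])
  tg <- seq(0, max(frame_end(sch2)), by = dt)
  for (rn in names(study$tissue_curves)) {
    fit <- first_tracer_fits[[rn]]
    if (is.null(fit) || is.null(fit$params)) {
      warning(sprintf("no first-tracer fit for region '%s'; skipped", rn))
      next
    }
    resid_grid <- evaluate_onetcm(fit$params, correction$input_fun_first,
                                  tg, dt)
    resid <- frame_avg_grid(tg, resid_grid, sch2)
    meas_unc <- decay_correct(study$tissue_curves[[rn]],
                              inj1$half_life_min,
                              study$tissue_curves[[rn]]$decay_reference,
                              "remove")
    meas2 <- subset_tac(meas_unc, idx$second)
    vals <- meas2$values - resid
    n_clipped[rn] <- sum(vals < 0)
    vals <- pmax(vals, 0)
    corrected[[rn]] <- decay_correct(tac(sch2, vals, region = rn),
                                     inj2$half_life_min, t2, "apply")
    projected[[rn]] <- tac(sch2, resid, region = rn)
  }
  structure(list(corrected_tissues = corrected,
                 projected_tissues = projected, n_clipped = n_clipped),
            class = "tissue_correction")
}

#' Residual signal fraction
#'
#' Percent of a measured value attributable to residual first-tracer
#' signal: \code{100 * (measured - corrected) / measured}.  The same
#' convention (uncorrected value as denominator) is used for comparisons of
#' kinetic-parameter estimates.
#'
#' @param measured measured (uncorrected) value(s), > 0.
#' @param corrected corrected value(s).
#' @return Percent difference(s).
#' @examples
#' residual_fraction(3.18, 2.99)   # ~6 percent
#' @export
residual_fraction <- function(measured, corrected) {
  if (any(measured <= 0)) stop("'measured' must be > 0")
  100 * (measured - corrected) / measured
}

#' Fit the second tracer on (corrected) second-segment curves
#'
#' Re-zeroes the time axis to the second injection and runs the 2-tissue
#' irreversible compartment fit plus the Patlak estimator.
#'
#' @param tissue second-segment tissue \code{tac}, decay-corrected to the
#'   second injection, on the study clock.
#' @param input matching input \code{tac}.
#' @param t2 second injection time (minutes, study clock).
#' @param options a \code{\link{fit_options}}.
#' @param method compartment fit method (see \code{\link{fit_tcm}}).
#' @param t_star_patlak Patlak t*, minutes after the second injection.
#' @return List with \code{compartment} (\code{tcm_fit}) and \code{patlak}
#'   (\code{graphical_fit}).
#' @export
fit_second_tracer <- function(tissue, input, t2, options = fit_options(),
                              method = "separable", t_star_patlak = 20) {
  tz <- shift_tac(tissue, -t2)
  iz <- shift_tac(input, -t2)
  list(compartment = fit_tcm(tz, iz, model = "2tcm-irrev",
                             method = method, options = options),
       patlak = patlak_ki(tz, iz, t_star = t_star_patlak))
}

#' Simultaneous dual-tracer fit
#'
#' Fits both tracers' compartment models in one weighted least-squares
#' problem over the full schedule, in the decay-uncorrected domain, using
#' the separable strategy: the nonlinear parameters are \code{k2} of the
#' first (reversible) tracer, \code{theta = k2 + k3} of the second
#' (irreversible) tracer and an optional shared input delay; all remaining
#' parameters are linear coefficients solved by nonnegative least squares
#' at each nonlinear point.  Since a tracer's decay-corrected convolution
#' times its decay factor equals the convolution of its decay-uncorrected
#' input at rate \code{k + lambda}, the design matrix is built directly
#' from the decay-uncorrected per-tracer input components (obtained from
#' the input-correction step).  The blood signal being physically shared, a
#' single blood-fraction coefficient multiplies the measured dual-tracer
#' blood curve.
#'
#' @param study a \code{dual_tracer_study}.
#' @param region region to fit (default first region).
#' @param options a \code{\link{fit_options}}; the joint fit defaults to no
#'   delay search (\code{delay_grid = 0}).
#' @param correction optionally a precomputed \code{input_correction}.
#' @param triexp_fit_start see \code{\link{correct_input_function}}.
#' @return List of class \code{joint_dual_fit} with \code{tracer1}
#'   (\code{onetcm_params} + V_T), \code{tracer2} (\code{twotcm_params} +
#'   K_i), shared \code{vB}, \code{objective}, \code{converged},
#'   \code{method_tag}.
#' @export
joint_dual_fit <- function(study, region = names(study$tissue_curves)[1],
                           options = fit_options(delay_grid = 0),
                           correction = NULL, triexp_fit_start = 5) {
  if (!inherits(study, "dual_tracer_study"))
    stop("'study' must be a dual_tracer_study")
  if (is.null(correction))
    correction <- correct_input_function(study, triexp_fit_start)
  inj1 <- study$injections[[1]]; inj2 <- study$injections[[2]]
  lam1 <- log(2) / inj1$half_life_min
  lam2 <- log(2) / inj2$half_life_min
  idx <- correction$indices
  if (length(idx$second) < 3L)
    stop("second segment too short for a joint fit")
  keep <- sort(c(idx$first, idx$second))
  sch <- study$input_curve$schedule
  sch_k <- frame_schedule(sch$start[keep], sch$duration[keep])
  meas_t <- decay_correct(study$tissue_curves[[region]],
                          inj1$half_life_min,
                          study$tissue_curves[[region]]$decay_reference,
                          "remove")
  y <- meas_t$values[keep]
  cb <- correction$uncorrected_input$values[keep]
  # the single-tracer weighting scheme transported to the decay-uncorrected
  # domain: w * exp(+2 lambda t) makes the weighted objective of an
  # uncorrected-domain residual identical to the corrected-domain one
  w <- fit_weights(sch_k, options)
  if (options$weighting == "duration-decay")
    w <- w * exp(2 * lam1 * (frame_mid(sch_k) - inj1$time_min))
  dt <- options$dt
  vb_max <- options$bounds$vB[2]
  tmax <- max(frame_end(sch_k))

  best <- NULL
  for (d in options$delay_grid) {
    g1 <- input_on_grid(correction$input_fun_first, tmax, d, dt)
    g2 <- input_on_grid(correction$input_fun_second, tmax, d, dt)
    tg <- g1$tg
    c2 <- frame_avg_grid(tg, exp_conv_grid(g2$cp, dt, lam2), sch_k)
    basis <- function(k2, theta) cbind(
      frame_avg_grid(tg, exp_conv_grid(g1$cp, dt, k2 + lam1), sch_k),
      c2,
      frame_avg_grid(tg, exp_conv_grid(g2$cp, dt, theta + lam2), sch_k),
      cb)
    obj <- function(p) {
      wnnls(basis(exp(p[1]), exp(p[2])), y, w, vb_max)$obj
    }
    lg <- seq(log(0.02), log(2), length.out = 7)
    grid <- as.matrix(expand.grid(lg, lg))
    vals <- apply(grid, 1, obj)
    p0 <- grid[which.min(vals), ]
    op <- stats::optim(p0, obj, method = "Nelder-Mead",
                       control = list(maxit = 200, reltol = 1e-10))
    if (is.null(best) || op$value < best$value) {
      best <- op; best$delay <- d
    }
  }
  d <- best$delay
  g1 <- input_on_grid(correction$input_fun_first, tmax, d, dt)
  g2 <- input_on_grid(correction$input_fun_second, tmax, d, dt)
  tg <- g1$tg
  k2_1 <- unname(exp(best$par[1])); theta <- unname(exp(best$par[2]))
  X <- cbind(
    frame_avg_grid(tg, exp_conv_grid(g1$cp, dt, k2_1 + lam1), sch_k),
    frame_avg_grid(tg, exp_conv_grid(g2$cp, dt, lam2), sch_k),
    frame_avg_grid(tg, exp_conv_grid(g2$cp, dt, theta + lam2), sch_k),
    cb)
  sol <- wnnls(X, y, w, vb_max)
  b1 <- sol$coef[1]; a1 <- sol$coef[2]; a2 <- sol$coef[3]
  vB <- sol$coef[4]
  b1 <- unname(b1); a1 <- unname(a1); a2 <- unname(a2); vB <- unname(vB)
  tr1 <- list(params = onetcm_params(b1 / max(1 - vB, 1e-8), k2_1, vB, d))
  tr1$macro <- macro_params(tr1$params)
  tr2 <- if (a1 + a2 > 0) {
    p <- twotcm_params((a1 + a2) / max(1 - vB, 1e-8),
                       max(theta * a2 / (a1 + a2), 1e-8),
                       theta * a1 / (a1 + a2), vB, d)
    list(params = p, macro = macro_params(p))
  } else list(params = NULL, macro = list(K_i = NA_real_))
  structure(list(region = region, tracer1 = tr1, tracer2 = tr2, vB = vB,
                 objective = sol$obj,
                 converged = best$convergence == 0 &&
                   !is.null(tr2$params),
                 n_iter = unname(best$counts[1]),
                 method_tag = "separable-joint",
                 correction = correction),
            class = "joint_dual_fit")
}

#' @export
print.joint_dual_fit <- function(x, ...) {
  cat(sprintf("Joint dual-tracer fit, region '%s' (%s)\n", x$region,
              x$method_tag))
  cat(sprintf("  tracer 1 (1TCM): K1=%.4g k2=%.4g V_T=%.4g\n",
              x$tracer1$params$K1, x$tracer1$params$k2,
              x$tracer1$macro$V_T))
  if (!is.null(x$tracer2$params))
    cat(sprintf("  tracer 2 (2TCM-irrev): K1=%.4g k2=%.4g k3=%.4g K_i=%.5g\n",
                x$tracer2$params$K1, x$tracer2$params$k2,
                x$tracer2$params$k3, x$tracer2$macro$K_i))
  else cat("  tracer 2: no signal attributed (zero coefficients)\n")
  cat(sprintf("  shared vB=%.4g, objective=%.5g, converged: %s\n",
              x$vB, x$objective, x$converged))
  invisible(x)
}
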