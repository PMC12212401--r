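#' Default dynamic frame schedules
#'
#' \code{default_dual_schedule()} is the schedule used for simulated
#' dual-tracer studies: a 29-min first segment (12 x 10 s, 6 x 30 s,
#' 5 x 60 s, 4 x 4 min, 1 x 3 min) with fine framing restarting at the
#' second injection and ending with 5-min frames at 89 min (6 x 30 s,
#' 4 x 60 s, 2 x 4 min, 9 x 5 min).  \code{default_single_schedule()} is a
#' 70-min single-tracer schedule (12 x 10 s, 6 x 30 s, 5 x 60 s, 15 x 4
#' min); \code{reduced_single_schedule()} is a coarser variant (23 frames)
#' for large subsampling grids.
#'
#' @param t2 second injection time in minutes (dual schedule only).
#' @return A \code{\link{frame_schedule}}.
#' @export
default_dual_schedule <- function(t2 = 29) {
  d1 <- c(rep(10 / 60, 12), rep(0.5, 6), rep(1, 5), rep(4, 4), 3)
  d1 <- d1 * t2 / sum(d1)   # keep the boundary exactly at t2
  d2 <- c(rep(0.5, 6), rep(1, 4), rep(4, 2), rep(5, 9))
  frame_schedule(cumsum(c(0, d1, d2[-length(d2)])), c(d1, d2))
}

#' @rdname default_dual_schedule
#' @export
default_single_schedule <- function() {
  d <- c(rep(10 / 60, 12), rep(0.5, 6), rep(1, 5), rep(4, 15))
  frame_schedule(cumsum(c(0, d[-length(d)])), d)
}

#' @rdname default_dual_schedule
#' @export
reduced_single_schedule <- function() {
  d <- c(rep(0.5, 6), rep(1, 4), 3, rep(5, 12))
  frame_schedule(cumsum(c(0, d[-length(d)])), d)
}

#' Input-function shape parameters
#'
#' The synthetic image-derived input function is, in the tracer's
#' decay-corrected domain and per MBq injected, \deqn{c(t') = \sum_i a_i
#' \left(e^{-L_i t'} - e^{-L_0 t'}\right), \quad t' = t - t_{inj} \ge 0,}
#' i.e. a bolus rising at rate \eqn{L_0} (peak about 0.5 min
#' post-injection) that washes out as a triexponential; the tail
#' (\eqn{t' > 5} min) is exactly triexponential, as assumed by the
#' residual-signal correction.
#'
#' @param amp_per_MBq tail amplitudes per MBq injected (kBq/mL/MBq).
#' @param rates tail decay rates (1/min), decreasing.
#' @param rise_rate bolus rise rate \eqn{L_0} (1/min).
#' @return A list of class \code{input_shape}.
#' @export
input_shape <- function(amp_per_MBq = c(0.45, 0.09, 0.03),
                        rates = c(0.5, 0.08, 0.01), rise_rate = 6) {
  if (length(amp_per_MBq) != 3L || length(rates) != 3L)
    stop("shape needs 3 amplitudes and 3 rates")
  if (any(amp_per_MBq < 0) || any(rates <= 0) || rise_rate <= 0)
    stop("invalid input shape")
  structure(list(amp_per_MBq = amp_per_MBq, rates = rates,
                 rise_rate = rise_rate), class = "input_shape")
}

#' Generate a synthetic blood input function
#'
#' @param injection an \code{\link{injection_event}}; the curve is zero
#'   before its injection time and scales linearly with its injected
#'   activity.
#' @param shape an \code{\link{input_shape}}.
#' @return A function of study-clock time (minutes) returning the
#'   decay-corrected (to the injection time) blood concentration in kBq/mL.
#' @export
generate_input_function <- function(injection, shape = input_shape()) {
  if (!inherits(injection, "injection_event"))
    stop("'injection' must be an injection_event")
  if (!inherits(shape, "input_shape")) stop("'shape' must be an input_shape")
  A <- shape$amp_per_MBq * injection$activity_MBq
  L <- shape$rates; L0 <- shape$rise_rate; ti <- injection$time_min
  function(t) {
    tt <- as.numeric(t) - ti
    out <- numeric(length(tt))
    ok <- tt >= 0
    if (any(ok))
      out[ok] <- colSums(A * (exp(-outer(L, tt[ok])) -
                                rep(exp(-L0 * tt[ok]), each = 3)))
    pmax(out, 0)
  }
}

#' Simulate a noiseless tissue time-activity curve
#'
#' Frame-averages the compartment-model forward curve driven by a continuous
#' input model, applies radioactive decay (relative to the injection time),
#' and returns the curve flagged decay-uncorrected.
#'
#' @param params a \code{onetcm_params} or \code{twotcm_params}.
#' @param input_fun continuous decay-corrected input model (function of
#'   study-clock minutes).
#' @param schedule a \code{frame_schedule}.
#' @param injection the \code{injection_event} (for decay and timing).
#' @param region region label.
#' @param dt quadrature step (minutes).
#' @return A decay-uncorrected \code{tac}.
#' @export
simulate_tissue_tac <- function(params, input_fun, schedule, injection,
                                region = "region", dt = 1 / 60) {
  lambda <- log(2) / injection$half_life_min
  model <- if (inherits(params, "onetcm_params")) evaluate_onetcm
           else evaluate_twotcm_irrev
  f <- function(t) {
    dec <- exp(-lambda * pmax(t - injection$time_min, 0))
    model(params, input_fun, t, dt) * dec
  }
  frame_average(f, schedule, dt = dt, region = region,
                decay_corrected = FALSE)
}

#' Add count-limited noise to a decay-uncorrected curve
#'
#' Adds zero-mean Gaussian noise with per-frame variance \deqn{\sigma_i^2 =
#' \mathrm{noise\_scale} \cdot C_i / \Delta t_i,} where \eqn{C_i} is the
#' decay-uncorrected frame value and \eqn{\Delta t_i} the frame duration in
#' minutes -- a Gaussian approximation to Poisson count statistics in which
#' the relative noise falls with injected activity and frame duration.
#' Negative values are clipped to 0.  Deterministic given \code{seed}.
#'
#' @param curve a decay-uncorrected \code{tac} with nonnegative values.
#' @param noise_scale variance scale, (kBq/mL) * min; 0 returns the curve
#'   unchanged.
#' @param seed integer seed; \code{NULL} uses (and advances) the current
#'   RNG stream.
#' @return A noisy \code{tac}.
#' @export
add_tac_noise <- function(curve, noise_scale, seed = NULL) {
  if (!inherits(curve, "tac")) stop("'curve' must be a tac")
  if (curve$decay_corrected)
    stop("noise is added in the decay-uncorrected (counts) domain")
  stopifnot_scalar(noise_scale, "noise_scale")
  if (noise_scale < 0) stop("'noise_scale' must be >= 0")
  if (any(curve$values < -1e-9)) stop("curve values must be nonnegative")
  if (noise_scale == 0) return(curve)
  sigma <- sqrt(noise_scale * pmax(curve$values, 0) /
                  curve$schedule$duration)
  draw <- function() curve$values + stats::rnorm(length(sigma), 0, sigma)
  v <- if (is.null(seed)) draw() else with_seed(seed, draw())
  tac(curve$schedule, pmax(v, 0), region = curve$region)
}

#' Synthetic ground truth for a tracer study
#'
#' Bundles everything the generator needs: injections, schedule, per-region
#' model parameters (one parameter set per injection), input shape, noise
#' scale and body weight.  The defaults mirror the dual-tracer protocol the
#' package targets: 41 MBq of a reversible tracer (1TCM, tumor V_T = 0.6
#' mL/cm^3) at t = 0 for 29 min, then 394 MBq of an irreversibly trapped
#' tracer (2TCM, tumor K_i = 0.016 mL/min/cm^3) for a further 60 min, body
#' weight 93.5 kg, both tracers 18F.
#'
#' @param injections list of 1 or 2 \code{\link{injection_event}}s ordered
#'   by time.
#' @param regions named list; each entry is a list of parameter sets
#'   (\code{onetcm_params}/\code{twotcm_params}), one per injection.
#' @param schedule a \code{\link{frame_schedule}} spanning all segments,
#'   with a frame boundary at the second injection time.
#' @param shape an \code{\link{input_shape}} shared by the tracers.
#' @param noise_scale see \code{\link{add_tac_noise}}; default 0.03.
#' @param body_weight kg.
#' @return A list of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(injections = list(
                              injection_event("FGln", 41, 0),
                              injection_event("FDG", 394, 29)),
                            regions = default_regions(length(injections)),
                            schedule = if (length(injections) == 2L)
                              default_dual_schedule(injections[[2]]$time_min)
                            else default_single_schedule(),
                            shape = input_shape(),
                            noise_scale = 0.03,
                            body_weight = 93.5) {
  if (!length(injections) %in% 1:2)
    stop("1 or 2 injections are supported")
  for (inj in injections)
    if (!inherits(inj, "injection_event"))
      stop("'injections' must be injection_event objects")
  if (length(injections) == 2L &&
      injections[[2]]$time_min <= injections[[1]]$time_min)
    stop("second injection must be strictly after the first")
  for (r in regions)
    if (length(r) != length(injections))
      stop("each region needs one parameter set per injection")
  structure(list(injections = injections, regions = regions,
                 schedule = schedule, shape = shape,
                 noise_scale = noise_scale, body_weight = body_weight),
            class = "synthetic_truth")
}

#' Default simulated organ set
#'
#' Literature-plausible compartment parameters for six regions; only the
#' tumor values are tied (in order of magnitude) to the protocol the
#' package targets.  With one injection only the reversible-tracer (1TCM)
#' parameters are returned.
#'
#' @param n_tracers 1 or 2.
#' @return Named list of per-region parameter lists.
#' @export
default_regions <- function(n_tracers = 2L) {
  fgln <- list(
    tumor       = onetcm_params(0.12, 0.20, vB = 0.05),
    gray_matter = onetcm_params(0.30, 0.60, vB = 0.04),
    kidney      = onetcm_params(0.60, 0.90, vB = 0.20),
    myocardium  = onetcm_params(0.50, 0.80, vB = 0.30),
    muscle      = onetcm_params(0.03, 0.06, vB = 0.02),
    spleen      = onetcm_params(0.80, 1.10, vB = 0.25))
  fdg <- list(
    tumor       = twotcm_params(0.10, 0.10, 0.019, vB = 0.05),
    gray_matter = twotcm_params(0.10, 0.13, 0.060, vB = 0.04),
    kidney      = twotcm_params(0.60, 1.00, 0.010, vB = 0.20),
    myocardium  = twotcm_params(0.60, 1.20, 0.080, vB = 0.30),
    muscle      = twotcm_params(0.03, 0.25, 0.015, vB = 0.02),
    spleen      = twotcm_params(0.80, 1.30, 0.005, vB = 0.25))
  if (n_tracers == 1L) lapply(fgln, list)
  else mapply(function(a, b) list(a, b), fgln, fdg, SIMPLIFY = FALSE)
}

# Noiseless decay-uncorrected per-injection components of a study.
simulate_components <- function(truth, dt = 1 / 60) {
  sch <- truth$schedule
  inj <- truth$injections
  cps <- lapply(inj, generate_input_function, shape = truth$shape)
  input_comp <- lapply(seq_along(inj), function(i) {
    lambda <- log(2) / inj[[i]]$half_life_min
    frame_average(function(t)
      cps[[i]](t) * exp(-lambda * pmax(t - inj[[i]]$time_min, 0)),
      sch, dt = dt, region = "blood")
  })
  tissue_comp <- lapply(names(truth$regions), function(rn) {
    lapply(seq_along(inj), function(i)
      simulate_tissue_tac(truth$regions[[rn]][[i]], cps[[i]], sch,
                          inj[[i]], region = rn, dt = dt))
  })
  names(tissue_comp) <- names(truth$regions)
  list(cp_funs = cps, input = input_comp, tissues = tissue_comp)
}

sum_tacs <- function(tacs) {
  v <- Reduce(`+`, lapply(tacs, `[[`, "values"))
  tac(tacs[[1]]$schedule, v, region = tacs[[1]]$region)
}

# Assemble measured decay-corrected curves from noiseless components:
# add noise (seed-deterministic), then decay-correct to the first injection.
assemble_study <- function(truth, comps, seed) {
  inj1 <- truth$injections[[1]]
  noisy_corr <- function(noiseless) {
    n <- add_tac_noise(noiseless, truth$noise_scale, seed = NULL)
    decay_correct(n, inj1$half_life_min, inj1$time_min, "apply")
  }
  build <- function() {
    input <- noisy_corr(sum_tacs(comps$input))
    tissues <- lapply(comps$tissues, function(tc) noisy_corr(sum_tacs(tc)))
    list(input = input, tissues = tissues)
  }
  m <- if (truth$noise_scale > 0) with_seed(seed, build()) else build()
  structure(list(injections = truth$injections, input_curve = m$input,
                 tissue_curves = m$tissues,
                 body_weight = truth$body_weight, truth = truth,
                 components = comps, seed = seed),
            class = c(if (length(truth$injections) == 2L)
                        "dual_tracer_study", "tracer_study"))
}

#' Simulate a dual-tracer (or single-tracer) study
#'
#' Sums the per-tracer decay-uncorrected signals of all regions and of the
#' blood input on a shared schedule with a frame boundary at the second
#' injection, adds count-limited noise, and decay-corrects the measured
#' curves to the first injection time.  The isolated noiseless per-tracer
#' components are retained in the object (see
#' \code{\link{study_components}}) as ground truth for oracle checks.  Same
#' truth and seed give an identical study; different seeds share identical
#' noiseless components.
#'
#' @param truth a \code{\link{synthetic_truth}} with two injections (one
#'   for \code{simulate_tracer_study}).
#' @param seed integer noise seed.
#' @param dt quadrature step (minutes).
#' @return A \code{dual_tracer_study} (class also \code{tracer_study}).
#' @export
simulate_dual_tracer_study <- function(truth, seed = 1, dt = 1 / 60) {
  if (length(truth$injections) != 2L)
    stop("'truth' must have two injections")
  t2 <- truth$injections[[2]]$time_min
  if (!any(abs(truth$schedule$start - t2) < 1e-6))
    stop("schedule must have a frame boundary at the second injection")
  assemble_study(truth, simulate_components(truth, dt), seed)
}

#' @rdname simulate_dual_tracer_study
#' @export
simulate_tracer_study <- function(truth, seed = 1, dt = 1 / 60)
  assemble_study(truth, simulate_components(truth, dt), seed)

#' Ground-truth components of a simulated study
#'
#' @param study a simulated \code{tracer_study}.
#' @return List with \code{cp_funs} (continuous decay-corrected input
#'   models), \code{input} and \code{tissues}: noiseless decay-uncorrected
#'   per-injection component curves.
#' @export
study_components <- function(study) {
  if (is.null(study$components)) stop("study carries no components")
  study$components
}

#' Emulate a lower injected dose by count thinning
#'
#' Emulates list-mode subsampling at the TAC level: the noiseless signal is
#' scaled by \code{fraction}, noise is regenerated at the thinned count
#' level, and the result is renormalized by \code{1/fraction}, so the
#' expected signal is unchanged while the noise variance scales as
#' \code{1/fraction}.  The injected-activity metadata is scaled by
#' \code{fraction}.  For a dual-tracer study only the first-segment frames
#' (the low-dose tracer's portion) are thinned, mirroring subsampling of
#' the first tracer's data; later frames are re-noised at the full level.
#'
#' @param study a simulated \code{tracer_study}.
#' @param fraction dose fraction in (0, 1].
#' @param seed noise seed.
#' @return A \code{tracer_study} with thinned measured curves.
#' @export
thin_dose <- function(study, fraction, seed = 1) {
  if (!inherits(study, "tracer_study"))
    stop("'study' must be a simulated tracer_study")
  stopifnot_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  truth <- study$truth
  comps <- study$components
  sch <- truth$schedule
  dual <- length(truth$injections) == 2L
  fvec <- if (dual) {
    t2 <- truth$injections[[2]]$time_min
    ifelse(frame_mid(sch) < t2, fraction, 1)
  } else rep(fraction, length(sch$start))
  inj1 <- truth$injections[[1]]
  thin_one <- function(noiseless) {
    scaled <- tac(sch, noiseless$values * fvec, region = noiseless$region)
    n <- add_tac_noise(scaled, truth$noise_scale, seed = NULL)
    renorm <- tac(sch, n$values / fvec, region = noiseless$region)
    decay_correct(renorm, inj1$half_life_min, inj1$time_min, "apply")
  }
  build <- function() {
    list(input = thin_one(sum_tacs(comps$input)),
         tissues = lapply(comps$tissues,
                          function(tc) thin_one(sum_tacs(tc))))
  }
  m <- if (truth$noise_scale > 0) with_seed(seed, build()) else build()
  inj <- truth$injections
  inj[[1]]$activity_MBq <- inj[[1]]$activity_MBq * fraction
  structure(list(injections = inj, input_curve = m$input,
                 tissue_curves = m$tissues,
                 body_weight = truth$body_weight, truth = truth,
                 components = comps, seed = seed,
                 dose_fraction = fraction),
            class = class(study))
}

#' @export
print.tracer_study <- function(x, ...) {
  inj <- x$injections
  cat(sprintf("%s study: %s\n",
              if (length(inj) == 2L) "Dual-tracer" else "Single-tracer",
              paste(vapply(inj, function(i)
                sprintf("%s %.1f MBq @ %.0f min", i$tracer,
                        i$activity_MBq, i$time_min), ""),
                collapse = " + ")))
  cat(sprintf("%d frames to %.0f min; regions: %s; body weight %.1f kg\n",
              length(x$input_curve$values),
              max(frame_end(x$input_curve$schedule)),
              paste(names(x$tissue_curves), collapse = ", "),
              x$body_weight))
  invisible(x)
}
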