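# Shared fixtures and independent oracles for the test suite.

# fast fit options: no delay search
opt0 <- fit_options(delay_grid = 0)

const_input <- function(c = 1) function(t) rep(c, length(t))

# a small uniform schedule for algebraic checks
toy_schedule <- function(n = 10, dt = 1) frame_schedule(dt * (0:(n - 1)),
                                                       rep(dt, n))

# default tumor-only truths (paper-matched dual protocol; single 263-MBq)
tumor_dual_truth <- function(noise_scale = 0.03)
  synthetic_truth(regions = default_regions(2)["tumor"],
                  noise_scale = noise_scale)

tumor_single_truth <- function(noise_scale = 0.03,
                               schedule = default_single_schedule(),
                               activity = 263,
                               params = onetcm_params(0.12, 0.2, vB = 0.05))
  synthetic_truth(injections = list(injection_event("FGln", activity, 0)),
                  regions = list(tumor = list(params)),
                  schedule = schedule, noise_scale = noise_scale)

# independent dense-grid convolution oracle: direct Riemann evaluation of
# (1-vB) K1 int_0^t h(t-s) cp(s) ds + vB cp(t), h the model's impulse
# response, on a dt-step grid.  Deliberately naive: O(n) sum per time point.
oracle_conv <- function(params, cp_fun, times, dt = 0.001) {
  vapply(times, function(t) {
    s <- seq(0, t, by = dt)
    cp <- cp_fun(s - params$delay)
    cp[s - params$delay < 0] <- 0
    if (inherits(params, "onetcm_params")) {
      h <- params$K1 * exp(-params$k2 * (t - s))
    } else {
      th <- params$k2 + params$k3
      h <- params$K1 * (params$k3 / th +
                          params$k2 / th * exp(-th * (t - s)))
    }
    free <- sum((h * cp)[-1] + (h * cp)[-length(s)]) * dt / 2
    cbv <- cp_fun(t - params$delay)
    (1 - params$vB) * free + params$vB *
      (if (t - params$delay >= 0) cbv else 0)
  }, numeric(1))
}

# noiseless framed curves for a model/input on a schedule, decay-corrected
framed_model_curve <- function(params, cp_fun, schedule) {
  ev <- if (inherits(params, "onetcm_params")) evaluate_onetcm
        else evaluate_twotcm_irrev
  frame_average(function(t) ev(params, cp_fun, t), schedule,
                decay_corrected = TRUE, decay_reference = 0)
}

framed_input_curve <- function(cp_fun, schedule)
  frame_average(cp_fun, schedule, region = "blood",
                decay_corrected = TRUE, decay_reference = 0)
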