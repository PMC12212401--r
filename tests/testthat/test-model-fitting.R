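test_that("noiseless generator-fitter round trip recovers 1TCM parameters", {
  sch <- default_single_schedule()
  cp <- generate_input_function(injection_event("FGln", 41, 0))
  truth <- onetcm_params(0.12, 0.2, vB = 0.05, delay = 0)
  ipt <- framed_input_curve(cp, sch)
  # generate with the same framed-input representation the fitter sees,
  # so the check isolates the estimator itself
  fin <- dualtracer:::as_input_fun(ipt)
  tiss <- framed_model_curve(truth, fin, sch)
  for (m in c("separable", "lm")) {
    f <- fit_tcm(tiss, ipt, "1tcm", method = m, options = opt0)
    expect_true(f$converged)
    expect_equal(f$params$K1, 0.12, tolerance = 1e-4)
    expect_equal(f$params$k2, 0.2, tolerance = 1e-4)
    expect_equal(f$params$vB, 0.05, tolerance = 1e-3)
    expect_equal(f$macro$V_T, 0.6, tolerance = 1e-4)
    expect_lt(f$objective, 1e-8)
  }
})

test_that("noiseless 2TCM-irreversible fit recovers K_i and the separable
           coefficients map back to the micro-parameters", {
  sch <- default_single_schedule()
  cp <- generate_input_function(injection_event("FDG", 394, 0))
  truth <- twotcm_params(0.1, 0.1, 0.02, vB = 0.05)
  ipt <- framed_input_curve(cp, sch)
  fin <- dualtracer:::as_input_fun(ipt)
  tiss <- framed_model_curve(truth, fin, sch)
  f <- fit_tcm(tiss, ipt, "2tcm-irrev", options = opt0)
  expect_true(f$converged)
  expect_equal(f$macro$K_i, 1 / 60, tolerance = 1e-3)
  expect_equal(f$params$K1, 0.1, tolerance = 1e-2)
  expect_equal(f$params$k3, 0.02, tolerance = 1e-2)
  flm <- fit_tcm(tiss, ipt, "2tcm-irrev", method = "lm", options = opt0)
  expect_equal(flm$macro$K_i, 1 / 60, tolerance = 1e-3)
})

test_that("separable and LM fits agree on macro-parameters for random
           noiseless truths", {
  sch <- default_single_schedule()
  cp <- generate_input_function(injection_event("FGln", 41, 0))
  ipt <- framed_input_curve(cp, sch)
  fin <- dualtracer:::as_input_fun(ipt)
  set.seed(7)
  for (i in 1:4) {
    truth <- onetcm_params(runif(1, 0.05, 0.3), runif(1, 0.1, 0.6),
                           vB = runif(1, 0, 0.2))
    tiss <- framed_model_curve(truth, fin, sch)
    fs <- fit_tcm(tiss, ipt, "1tcm", method = "separable", options = opt0)
    fl <- fit_tcm(tiss, ipt, "1tcm", method = "lm", options = opt0)
    expect_equal(fs$macro$V_T, fl$macro$V_T, tolerance = 0.01)
    expect_equal(fs$macro$V_T, macro_params(truth)$V_T, tolerance = 0.01)
  }
})

test_that("separable optimum is at least as good as the LM optimum on
           noisy curves", {
  truth <- tumor_single_truth()
  for (s in 1:5) {
    st <- simulate_tracer_study(truth, seed = s)
    fs <- fit_tcm(st$tissue_curves$tumor, st$input_curve, "1tcm",
                  method = "separable", options = opt0)
    fl <- fit_tcm(st$tissue_curves$tumor, st$input_curve, "1tcm",
                  method = "lm", options = opt0)
    expect_lte(fs$objective, fl$objective * 1.001)
  }
})

test_that("a blood-only curve is fit perfectly when vB may reach 1", {
  sch <- default_single_schedule()
  cp <- generate_input_function(injection_event("FGln", 41, 0))
  ipt <- framed_input_curve(cp, sch)
  opts <- fit_options(delay_grid = 0,
                      bounds = list(K1 = c(0, 5), k2 = c(1e-4, 5),
                                    k3 = c(0, 5), vB = c(0, 1)))
  f <- fit_tcm(ipt, ipt, "1tcm", options = opts)
  expect_equal(f$params$vB, 1, tolerance = 1e-3)
  expect_lt(f$objective, 1e-6 * sum(f$weights * ipt$values^2))
})

test_that("fitted parameters are invariant to joint rescaling of tissue
           and input under uniform weights", {
  truth <- tumor_single_truth()
  st <- simulate_tracer_study(truth, seed = 3)
  opts <- fit_options(weighting = "uniform", delay_grid = 0)
  f1 <- fit_tcm(st$tissue_curves$tumor, st$input_curve, "1tcm",
                options = opts)
  sc <- function(x, c) tac(x$schedule, x$values * c, region = x$region,
                           decay_corrected = x$decay_corrected,
                           decay_reference = x$decay_reference)
  f2 <- fit_tcm(sc(st$tissue_curves$tumor, 5), sc(st$input_curve, 5),
                "1tcm", options = opts)
  expect_equal(f1$params$K1, f2$params$K1, tolerance = 1e-6)
  expect_equal(f1$params$k2, f2$params$k2, tolerance = 1e-6)
  expect_equal(f2$objective, 25 * f1$objective, tolerance = 1e-6)
})

test_that("V_T estimator bias shrinks as the noise scale decreases", {
  errs <- sapply(c(0.06, 0.015, 0), function(ns) {
    truth <- tumor_single_truth(noise_scale = ns)
    vt <- sapply(1:8, function(s)
      fit_tcm(simulate_tracer_study(truth, seed = s)$tissue_curves$tumor,
              simulate_tracer_study(truth, seed = s)$input_curve,
              "1tcm", options = opt0)$macro$V_T)
    abs(median(vt) - 0.6)
  })
  expect_lt(errs[3], 0.01)          # noiseless essentially unbiased
  expect_lt(errs[2], errs[1] + 0.01)  # monotone within Monte-Carlo slack
})

test_that("an input shift is recovered on the delay grid", {
  truth <- synthetic_truth(
    injections = list(injection_event("FGln", 41, 0)),
    regions = list(tumor = list(onetcm_params(0.12, 0.2, vB = 0.05,
                                              delay = 0.5))),
    schedule = default_single_schedule(), noise_scale = 0)
  st <- simulate_tracer_study(truth, seed = 1)
  f <- fit_tcm(st$tissue_curves$tumor, st$input_curve, "1tcm",
               options = fit_options(delay_grid = seq(-1, 2, by = 0.1)))
  expect_equal(f$params$delay, 0.5, tolerance = 1e-9)
  expect_equal(f$macro$V_T, 0.6, tolerance = 0.01)
})

test_that("fit results carry the modelling-object interface", {
  truth <- tumor_single_truth()
  st <- simulate_tracer_study(truth, seed = 2)
  f <- fit_tcm(st$tissue_curves$tumor, st$input_curve, "1tcm",
               options = opt0)
  co <- coef(f)
  expect_true(all(c("K1", "k2", "vB", "delay", "V_T") %in% names(co)))
  expect_length(fitted(f), length(st$tissue_curves$tumor$values))
  expect_equal(residuals(f), st$tissue_curves$tumor$values - fitted(f))
  expect_equal(predict(f), fitted(f))
  expect_length(predict(f, newtimes = c(1, 10)), 2)
  s <- summary(f)
  expect_s3_class(s, "summary.tcm_fit")
  expect_false(any(is.na(s$table[, "Std. Error"])))
  expect_output(print(f), "1TCM fit")
})

test_that("triexponential fitting recovers nested and full models and
           extrapolates", {
  sch <- default_single_schedule()
  tm <- frame_mid(sch)
  # single exponential: nested model recovered with ~zero residual
  one <- tac(sch, 20 * exp(-0.1 * tm))
  f1 <- fit_triexp(one, fit_start = 2)
  expect_lt(f1$objective, 1e-6 * sum(one$values^2))
  # noiseless triexponential sampled as frame averages
  pars <- triexp_params(c(20, 5, 1), c(0.5, 0.08, 0.01), onset = 0)
  cur <- frame_average(function(t) evaluate_triexp(pars, t), sch)
  f3 <- fit_triexp(cur, fit_start = 2)
  expect_equal(predict(f3, 60), evaluate_triexp(pars, 60),
               tolerance = 0.02)
  # degenerate inputs
  expect_error(fit_triexp(tac(frame_schedule(0:5, rep(1, 6)), rep(1, 6)),
                          fit_start = 0), "at least 7")
  z <- fit_triexp(tac(sch, rep(0, length(tm))), fit_start = 2)
  expect_identical(z$objective, 0)
  expect_equal(z$params$A, c(0, 0, 0))
})
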