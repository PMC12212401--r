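test_that("frame schedules enforce ordering and non-overlap", {
  expect_error(frame_schedule(c(0, 0.5), c(1, 1)), "overlap")
  expect_error(frame_schedule(c(1, 0), c(0.5, 0.5)), "increasing")
  expect_error(frame_schedule(0, 0), "> 0")
  sch <- frame_schedule(c(0, 1, 2), c(1, 1, 2))
  expect_equal(frame_mid(sch), c(0.5, 1.5, 3))
  expect_equal(frame_end(sch), c(1, 2, 4))
})

test_that("tac objects validate values and decay state", {
  sch <- toy_schedule(4)
  expect_error(tac(sch, 1:3), "one entry per frame")
  expect_error(tac(sch, c(1, 2, NA, 4)), "finite")
  expect_error(tac(sch, 1:4, decay_corrected = TRUE), "decay_reference")
  x <- tac(sch, 1:4, decay_corrected = TRUE, decay_reference = 0)
  expect_true(x$decay_corrected)
})

test_that("1TCM evaluator matches closed forms", {
  # no uptake: pure blood signal
  p0 <- onetcm_params(0, 0.2, vB = 0.05)
  cp <- const_input(2)
  expect_equal(evaluate_onetcm(p0, cp, c(1, 5, 10)), rep(0.1, 3))
  # constant input closed form: (K1/k2)(1 - exp(-k2 t))
  p <- onetcm_params(0.1, 0.2)
  expect_equal(evaluate_onetcm(p, const_input(1), 5),
               0.5 * (1 - exp(-1)), tolerance = 1e-4)
  expect_error(evaluate_onetcm(p, const_input(1), -1), ">= 0")
  expect_error(onetcm_params(0.1, 0), "> 0")
})

test_that("2TCM-irreversible evaluator matches closed form and nests 1TCM", {
  p <- twotcm_params(0.1, 0.1, 0.02)
  # constant input closed form at t = 10
  want <- 0.1 * ((0.02 / 0.12) * 10 +
                   (0.1 / 0.12^2) * (1 - exp(-1.2)))
  expect_equal(evaluate_twotcm_irrev(p, const_input(1), 10), want,
               tolerance = 1e-4)
  # k3 = 0 reduces exactly to the 1-tissue model
  tri <- generate_input_function(injection_event("A", 41, 0))
  tt <- c(1, 5, 20, 45)
  p2 <- twotcm_params(0.12, 0.2, 0, vB = 0.03)
  p1 <- onetcm_params(0.12, 0.2, vB = 0.03)
  expect_equal(evaluate_twotcm_irrev(p2, tri, tt),
               evaluate_onetcm(p1, tri, tt), tolerance = 1e-10)
  # late-time slope under constant unit input tends to K_i
  t_late <- c(300, 301)
  slope <- diff(evaluate_twotcm_irrev(p, const_input(1), t_late))
  expect_equal(slope, macro_params(p)$K_i, tolerance = 1e-3)
})

test_that("model evaluators agree with a dense-grid convolution oracle", {
  tri <- generate_input_function(injection_event("A", 41, 0))
  set.seed(42)
  for (i in 1:8) {
    K1 <- runif(1, 0.01, 0.5); k2 <- runif(1, 0.05, 1)
    k3 <- runif(1, 0, 0.2); vB <- runif(1, 0, 0.2)
    tt <- sort(runif(4, 2, 60))
    p1 <- onetcm_params(K1, k2, vB)
    expect_equal(evaluate_onetcm(p1, tri, tt, dt = 1 / 120),
                 oracle_conv(p1, tri, tt), tolerance = 1e-3)
    p2 <- twotcm_params(K1, k2, k3, vB)
    expect_equal(evaluate_twotcm_irrev(p2, tri, tt, dt = 1 / 120),
                 oracle_conv(p2, tri, tt), tolerance = 1e-3)
  }
})

test_that("blood-free model output is linear in the input scale", {
  tri <- generate_input_function(injection_event("A", 41, 0))
  tri3 <- function(t) 3 * tri(t)
  p <- onetcm_params(0.12, 0.2)
  tt <- c(2, 10, 40)
  expect_equal(evaluate_onetcm(p, tri3, tt),
               3 * evaluate_onetcm(p, tri, tt), tolerance = 1e-12)
})

test_that("input delay shifts the model rightward with zero fill", {
  tri <- generate_input_function(injection_event("A", 41, 0))
  p0 <- onetcm_params(0.12, 0.2, delay = 0)
  pd <- onetcm_params(0.12, 0.2, delay = 2)
  tt <- c(5, 20, 50)
  expect_equal(evaluate_onetcm(pd, tri, tt + 2),
               evaluate_onetcm(p0, tri, tt), tolerance = 1e-6)
  expect_equal(evaluate_onetcm(pd, tri, 1), 0)  # before delayed onset
})

test_that("decay correction round-trips, halves at one half-life and
           re-references by a constant factor", {
  sch <- frame_schedule(c(0, 50, 109.77 - 2), c(4, 4, 4))
  x <- tac(sch, c(1, 1, 1), decay_corrected = TRUE, decay_reference = 0)
  unc <- decay_correct(x, 109.77, 0, "remove")
  # frame with mid-time at exactly one half-life drops to 0.5
  expect_equal(unc$values[3], 0.5)
  back <- decay_correct(unc, 109.77, 0, "apply")
  expect_equal(back$values, x$values, tolerance = 1e-12)
  # state flag forbids double application
  expect_error(decay_correct(x, 109.77, 0, "apply"), "twice")
  expect_error(decay_correct(unc, 109.77, 0, "remove"), "not decay")
  # re-referencing changes every frame by exp(-lambda * 29)
  re29 <- decay_correct(unc, 109.77, 29, "apply")
  expect_equal(re29$values / x$values,
               rep(exp(-log(2) / 109.77 * 29), 3), tolerance = 1e-12)
})

test_that("frame averaging is exact for constants and linear curves and
           accurate for exponentials", {
  sch <- frame_schedule(c(0, 2, 4), c(2, 2, 2))
  expect_equal(frame_average(function(t) rep(7, length(t)), sch)$values,
               rep(7, 3))
  a <- 0.3
  expect_equal(frame_average(function(t) a * t, sch)$values,
               a * frame_mid(sch), tolerance = 1e-10)
  one <- frame_schedule(0, 4)
  expect_equal(frame_average(function(t) exp(-0.2 * t), one)$values,
               (1 - exp(-0.8)) / 0.8, tolerance = 1e-6)
  expect_error(frame_average(function(t) rep(NA_real_, length(t)), one),
               "not defined")
})

test_that("macro-parameters follow their closed forms", {
  expect_equal(macro_params(onetcm_params(0.12, 0.2))$V_T, 0.6)
  expect_equal(macro_params(twotcm_params(0.1, 0.1, 0.02))$K_i, 1 / 60)
  expect_equal(macro_params(twotcm_params(0.1, 0.1, 0))$K_i, 0)
})

test_that("SUV normalizes concentration by dose per body weight", {
  sch <- frame_schedule(0, 5)
  inj <- injection_event("FDG", 394, 0)
  x <- tac(sch, 12.5, decay_corrected = TRUE, decay_reference = 0)
  expect_equal(compute_suv(x, inj, 93.5), 12.5 * 93.5 / 394,
               tolerance = 1e-12)
  # identity: concentration equal to dose/weight gives SUV 1; zero gives 0
  y <- tac(sch, 394 / 93.5, decay_corrected = TRUE, decay_reference = 0)
  expect_equal(compute_suv(y, inj, 93.5), 1)
  z <- tac(sch, 0, decay_corrected = TRUE, decay_reference = 0)
  expect_equal(compute_suv(z, inj, 93.5), 0)
  expect_error(compute_suv(x, inj, -1), "> 0")
  unc <- tac(sch, 12.5)
  expect_error(compute_suv(unc, inj, 93.5), "decay-corrected")
})

test_that("TAC CSV and study JSON round-trip through files", {
  sch <- default_single_schedule()
  cp <- generate_input_function(injection_event("FGln", 41, 0))
  curves <- list(blood = framed_input_curve(cp, sch),
                 tumor = framed_model_curve(onetcm_params(0.12, 0.2, 0.05),
                                            cp, sch))
  curves$tumor$region <- "tumor"
  f <- tempfile(fileext = ".csv")
  write_tac_csv(curves, f)
  back <- read_tac_csv(f)
  expect_named(back, c("blood", "tumor"))
  expect_equal(back$tumor$values, curves$tumor$values, tolerance = 1e-12)
  expect_true(back$blood$decay_corrected)
  expect_equal(back$blood$decay_reference, 0)

  g <- tempfile(fileext = ".json")
  write_study_json(list(injection_event("FGln", 41, 0),
                        injection_event("FDG", 394, 29)),
                   93.5, "blood", g)
  desc <- read_study_json(g)
  expect_equal(desc$injections[[2]]$activity_MBq, 394)
  expect_equal(desc$body_weight, 93.5)
  expect_equal(desc$input_region, "blood")
})
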