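test_that("segmentation respects the half-open convention and rejects
           degenerate splits", {
  truth <- tumor_dual_truth(noise_scale = 0)
  st <- simulate_dual_tracer_study(truth, seed = 1)
  seg <- segment_study(st)
  expect_equal(max(frame_end(seg$first$input$schedule)), 29)
  expect_equal(seg$second$input$schedule$start[1], 29)  # boundary at t2
  expect_equal(max(frame_end(seg$second$input$schedule)), 89)
  # second injection beyond the scan is rejected
  bad <- st
  bad$injections[[2]]$time_min <- 200
  expect_error(segment_study(bad), "span|empty")
  # a straddling frame is dropped with a warning
  sch <- frame_schedule(c(0, 10, 27, 31), c(10, 17, 4, 5))
  mk <- function() tac(sch, c(1, 1, 1, 1), decay_corrected = TRUE,
                       decay_reference = 0)
  st2 <- dual_tracer_study(st$injections, mk(), list(tumor = mk()), 93.5)
  expect_warning(s2 <- segment_study(st2), "straddle")
  expect_equal(length(s2$first$input$values) +
                 length(s2$second$input$values), 3)
})

test_that("projection and corrected curves conserve the measured signal", {
  truth <- tumor_dual_truth()
  st <- simulate_dual_tracer_study(truth, seed = 3)
  corr <- correct_input_function(st)
  meas_unc <- decay_correct(st$input_curve, 109.77, 0, "remove")
  meas2 <- meas_unc$values[corr$indices$second]
  corr_unc <- decay_correct(corr$corrected_input, 109.77, 29, "remove")
  # measured = projected + corrected frame-wise (before clipping; none
  # clipped here)
  expect_equal(corr$n_clipped, 0)
  expect_equal(corr_unc$values + corr$projection$values, meas2,
               tolerance = 1e-10)
})

test_that("a null first tracer makes the whole correction the identity", {
  truth <- synthetic_truth(
    injections = list(injection_event("FGln", 1e-9, 0),
                      injection_event("FDG", 394, 29)),
    regions = default_regions(2)["tumor"], noise_scale = 0)
  st <- simulate_dual_tracer_study(truth, seed = 1)
  corr <- correct_input_function(st)
  meas_unc <- decay_correct(st$input_curve, 109.77, 0, "remove")
  meas2 <- meas_unc$values[corr$indices$second]
  corr_unc <- decay_correct(corr$corrected_input, 109.77, 29, "remove")
  expect_equal(corr_unc$values, meas2, tolerance = 1e-8)
  # tissue correction is zero too
  rep <- run_dual_tracer_analysis(st, config = list(options = opt0))
  expect_lt(abs(rep$residual["tumor", "residual_pct_last"]), 0.01)
  expect_equal(rep$ki["tumor", "ki_corrected"],
               rep$ki["tumor", "ki_uncorrected"], tolerance = 1e-6)
})

test_that("the corrected input and tissue match the isolated second-tracer
           ground truth on a noiseless study", {
  truth <- tumor_dual_truth(noise_scale = 0)
  st <- simulate_dual_tracer_study(truth, seed = 1)
  comp <- study_components(st)
  rep <- run_dual_tracer_analysis(st, config = list(options = opt0))
  corr <- rep$correction
  late <- frame_mid(corr$corrected_input$schedule) >= 39  # >= t2 + 10 min
  true_in <- comp$input[[2]]$values[corr$indices$second]
  got_in <- decay_correct(corr$corrected_input, 109.77, 29,
                          "remove")$values
  expect_lt(max(abs(got_in[late] - true_in[late]) / true_in[late]), 0.03)
  true_ti <- comp$tissues$tumor[[2]]$values[corr$indices$second]
  got_ti <- decay_correct(rep$tissue_correction$corrected_tissues$tumor,
                          109.77, 29, "remove")$values
  expect_lt(max(abs(got_ti[late] - true_ti[late]) / true_ti[late]), 0.05)
})

test_that("a null second injection leaves near-zero corrected signal", {
  truth <- synthetic_truth(
    injections = list(injection_event("FGln", 41, 0),
                      injection_event("FDG", 1e-9, 29)),
    regions = default_regions(2)["tumor"], noise_scale = 0)
  st <- simulate_dual_tracer_study(truth, seed = 1)
  corr <- correct_input_function(st)
  peak1 <- max(study_components(st)$input[[1]]$values)
  resid <- decay_correct(corr$corrected_input, 109.77, 29, "remove")$values
  expect_lt(max(abs(resid)) / peak1, 0.05)
})

test_that("percent-difference convention reproduces worked examples", {
  expect_equal(round(residual_fraction(3.18, 2.99)), 6)
  # K_i change quoted against the uncorrected estimate
  expect_equal(round(abs(residual_fraction(0.0144, 0.0157))), 9)
  expect_equal(residual_fraction(5, 5), 0)
  expect_error(residual_fraction(0, 1), "> 0")
})

test_that("residual projection of a perfusion-free region is blood only", {
  truth <- synthetic_truth(
    regions = list(novasc = list(onetcm_params(0, 1, vB = 0.1),
                                 twotcm_params(0.1, 0.1, 0.02, vB = 0.1))),
    noise_scale = 0)
  st <- simulate_dual_tracer_study(truth, seed = 1)
  corr <- correct_input_function(st)
  fits <- list(novasc = fit_tcm(
    dualtracer:::subset_tac(decay_correct(st$tissue_curves$novasc, 109.77,
                                          0, "remove"),
                            corr$indices$first),
    dualtracer:::subset_tac(corr$uncorrected_input, corr$indices$first),
    "1tcm", options = fit_options(delay_grid = 0, weighting = "uniform")))
  tc <- subtract_tissue_residual(st, fits, corr)
  # projected residual equals vB times the projected blood curve
  sch2 <- tc$projected_tissues$novasc$schedule
  proj_blood <- frame_average(function(t)
    evaluate_onetcm(onetcm_params(0, 1, vB = fits$novasc$params$vB,
                                  delay = fits$novasc$params$delay),
                    corr$input_fun_first, t), sch2)$values
  expect_equal(tc$projected_tissues$novasc$values, proj_blood,
               tolerance = 0.02)
  # a region without a fit is skipped with a warning
  expect_warning(subtract_tissue_residual(st, list(), corr), "skipped")
})

test_that("joint fit degenerates to the single-tracer fit without a second
           tracer and matches the subtraction pipeline when noiseless", {
  truth0 <- synthetic_truth(
    injections = list(injection_event("FGln", 41, 0),
                      injection_event("FDG", 1e-9, 29)),
    regions = default_regions(2)["tumor"], noise_scale = 0)
  st0 <- simulate_dual_tracer_study(truth0, seed = 1)
  jf0 <- joint_dual_fit(st0)
  sf <- fit_tcm(st0$tissue_curves$tumor, st0$input_curve, "1tcm",
                options = opt0)
  expect_equal(jf0$tracer1$macro$V_T, sf$macro$V_T, tolerance = 1e-3)
  # noiseless default study: joint and subtraction agree on macro params
  truth <- tumor_dual_truth(noise_scale = 0)
  st <- simulate_dual_tracer_study(truth, seed = 1)
  rep <- run_dual_tracer_analysis(st, config = list(options = opt0))
  expect_equal(rep$joint$tracer2$macro$K_i, rep$ki["tumor", "ki_corrected"],
               tolerance = 0.02)
  expect_equal(rep$joint$tracer1$macro$V_T, rep$vt["tumor", "vt_1tcm"],
               tolerance = 0.02)
})

test_that("the end-to-end report is complete, deterministic and shows the
           corrected > uncorrected K_i direction", {
  truth <- tumor_dual_truth()
  st <- simulate_dual_tracer_study(truth, seed = 7)
  rep <- run_dual_tracer_analysis(st, config = list(options = opt0))
  expect_true(all(c("vt_1tcm", "vt_logan") %in% colnames(rep$vt)))
  expect_true(all(c("ki_corrected", "ki_uncorrected",
                    "ki_patlak_corrected") %in% colnames(rep$ki)))
  expect_true(all(c("suv_uncorrected_last", "suv_corrected_last",
                    "residual_pct_last") %in% colnames(rep$residual)))
  expect_gt(rep$residual["tumor", "residual_pct_last"], 0)
  expect_gt(rep$ki["tumor", "ki_corrected"],
            rep$ki["tumor", "ki_uncorrected"])
  # determinism: same seed, same numbers
  rep2 <- run_dual_tracer_analysis(simulate_dual_tracer_study(truth, 7),
                                   config = list(options = opt0))
  expect_identical(rep$ki, rep2$ki)
  expect_identical(rep$vt, rep2$vt)
  f <- tempfile(fileext = ".json")
  write_report(rep, f)
  expect_true(file.exists(f))
  parsed <- jsonlite::read_json(f)
  expect_true(!is.null(parsed$joint$ki))
})

test_that("correction accuracy improves with the dose ratio", {
  errs <- sapply(c(2, 5, 10, 20), function(ratio) {
    truth <- synthetic_truth(
      injections = list(injection_event("FGln", 41, 0),
                        injection_event("FDG", 41 * ratio, 29)),
      regions = default_regions(2)["tumor"], noise_scale = 0.03)
    err <- sapply(1:6, function(s) {
      st <- simulate_dual_tracer_study(truth, seed = s)
      comp <- study_components(st)
      corr <- correct_input_function(st)
      true2 <- comp$input[[2]]$values[corr$indices$second]
      got <- decay_correct(corr$corrected_input, 109.77, 29,
                           "remove")$values
      late <- frame_mid(corr$corrected_input$schedule) >= 39
      # relative error of the recovered second-tracer input
      mean(abs(got[late] - true2[late]) / true2[late])
    })
    mean(err)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("a study is reconstructed faithfully from CSV + JSON files", {
  truth <- tumor_dual_truth()
  st <- simulate_dual_tracer_study(truth, seed = 2)
  fc <- tempfile(fileext = ".csv"); fj <- tempfile(fileext = ".json")
  write_tac_csv(c(list(blood = st$input_curve), st$tissue_curves), fc)
  write_study_json(st$injections, st$body_weight, "blood", fj)
  st2 <- read_dual_tracer_study(fj, fc)
  expect_s3_class(st2, "dual_tracer_study")
  expect_equal(st2$input_curve$values, st$input_curve$values,
               tolerance = 1e-10)
  expect_equal(st2$tissue_curves$tumor$values,
               st$tissue_curves$tumor$values, tolerance = 1e-10)
})
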