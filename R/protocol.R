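#' Truncate a dynamic acquisition
#'
#' Keeps the frames lying entirely within \code{[start, duration]} minutes,
#' emulating a shorter scan.
#'
#' @param curve a \code{tac}.
#' @param duration scan duration in minutes (must retain at least one
#'   frame).
#' @return The truncated \code{tac}.
#' @export
truncate_scan <- function(curve, duration) {
  if (!inherits(curve, "tac")) stop("'curve' must be a tac")
  stopifnot_scalar(duration, "duration", positive = TRUE)
  keep <- which(frame_end(curve$schedule) <= duration + 1e-9)
  if (!length(keep)) stop("no frames survive the truncation")
  subset_tac(curve, keep)
}

#' Estimator stability versus injected dose and scan duration
#'
#' The protocol-design subsampling study: for every combination of dose
#' fraction, scan duration and replicate, the study is dose-thinned
#' (\code{\link{thin_dose}}), truncated (\code{\link{truncate_scan}}), and
#' the volume of distribution is re-estimated by the 1-tissue compartment
#' fit and the Logan plot.  Each estimate is reported as a percent
#' deviation from the same replicate's full-dose, full-duration reference,
#' so the reference cell deviates by exactly 0.  Within a replicate all
#' cells share one noise stream (the analog of subsampling one acquisition).
#' Per-cell fit failures are recorded as \code{NA}, not fatal.
#'
#' @param truth a single-tracer \code{\link{synthetic_truth}}.
#' @param dose_fractions vector of fractions in (0, 1].
#' @param durations scan durations in minutes, within the schedule support.
#' @param n_replicates noise replicates per cell (default 25).
#' @param base_seed integer; replicate r uses seed \code{base_seed + r}.
#' @param region region analysed (default the first).
#' @param t_star_logan Logan t* in minutes; capped at half the truncated
#'   duration so short scans remain analysable.
#' @param options a \code{\link{fit_options}} (default: separable fit, no
#'   delay search).
#' @return A data frame of class \code{stability_table} with columns
#'   \code{dose_fraction}, \code{duration_min}, \code{replicate},
#'   \code{seed}, \code{vt_1tcm}, \code{vt_logan}, \code{dev_1tcm_pct},
#'   \code{dev_logan_pct}.
#' @export
stability_analysis <- function(truth, dose_fractions, durations,
                               n_replicates = 25, base_seed = 1,
                               region = names(truth$regions)[1],
                               t_star_logan = 15,
                               options = fit_options(delay_grid = 0)) {
  if (length(truth$injections) != 1L)
    stop("'truth' must describe a single-tracer study")
  if (any(dose_fractions <= 0 | dose_fractions > 1))
    stop("'dose_fractions' must lie in (0, 1]")
  full_dur <- max(frame_end(truth$schedule))
  if (any(durations > full_dur + 1e-9))
    stop("'durations' must lie within the scan support")
  base <- simulate_tracer_study(truth, seed = base_seed)

  one_fit <- function(tiss, inp, dur) {
    vt1 <- tryCatch({
      f <- fit_tcm(tiss, inp, model = "1tcm", options = options)
      if (f$converged) unname(f$macro$V_T) else NA_real_
    }, error = function(e) NA_real_)
    vtl <- tryCatch(
      logan_vt(tiss, inp, t_star = min(t_star_logan, 0.4 * dur))$slope,
      error = function(e) NA_real_)
    c(vt1, vtl)
  }

  rows <- vector("list", n_replicates * length(dose_fractions) *
                   length(durations))
  k <- 0L
  for (r in seq_len(n_replicates)) {
    seed_r <- base_seed + r
    ref_study <- thin_dose(base, 1, seed = seed_r)
    ref <- one_fit(ref_study$tissue_curves[[region]],
                   ref_study$input_curve, full_dur)
    for (f in dose_fractions) {
      st <- if (f == 1) ref_study else thin_dose(base, f, seed = seed_r)
      for (dur in durations) {
        est <- one_fit(truncate_scan(st$tissue_curves[[region]], dur),
                       truncate_scan(st$input_curve, dur), dur)
        k <- k + 1L
        rows[[k]] <- data.frame(
          dose_fraction = f, duration_min = dur, replicate = r,
          seed = seed_r, vt_1tcm = est[1], vt_logan = est[2],
          dev_1tcm_pct = 100 * (est[1] - ref[1]) / ref[1],
          dev_logan_pct = 100 * (est[2] - ref[2]) / ref[2])
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- c(dose_fraction = 1, duration_min = full_dur)
  attr(out, "region") <- region
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Summarize a stability table
#'
#' @param object a \code{stability_table}.
#' @param ... unused.
#' @return Data frame with per-cell mean and standard deviation of the V_T
#'   estimates and of their percent deviations.
#' @export
summary.stability_table <- function(object, ...) {
  agg <- function(v, f) stats::aggregate(
    v, by = list(dose_fraction = object$dose_fraction,
                 duration_min = object$duration_min), FUN = f,
    na.rm = TRUE)
  out <- agg(object$vt_1tcm, mean)
  names(out)[3] <- "vt_1tcm_mean"
  out$vt_1tcm_sd <- agg(object$vt_1tcm, stats::sd)$x
  out$dev_1tcm_mean_pct <- agg(object$dev_1tcm_pct, mean)$x
  out$vt_logan_mean <- agg(object$vt_logan, mean)$x
  out$vt_logan_sd <- agg(object$vt_logan, stats::sd)$x
  out
}

#' @export
plot.stability_table <- function(x, ...) {
  s <- summary(x)
  durs <- sort(unique(s$duration_min))
  cols <- seq_along(durs)
  graphics::plot(range(s$dose_fraction), range(s$vt_1tcm_sd, na.rm = TRUE),
                 type = "n", log = "x", xlab = "dose fraction",
                 ylab = "SD of V_T estimate",
                 main = "V_T stability vs dose and duration", ...)
  for (i in seq_along(durs)) {
    d <- s[s$duration_min == durs[i], ]
    graphics::lines(d$dose_fraction, d$vt_1tcm_sd, col = cols[i], lwd = 2)
    graphics::points(d$dose_fraction, d$vt_1tcm_sd, col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = sprintf("%g min", durs),
                   col = cols, lwd = 2)
  invisible(x)
}
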