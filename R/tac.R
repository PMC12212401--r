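#' Dynamic frame schedule
#'
#' A frame schedule records the start time and duration of every frame of a
#' dynamic PET acquisition, in minutes on the study clock.  All time-activity
#' curves of a study share one schedule.
#'
#' @param start numeric vector of frame start times (minutes), strictly
#'   increasing.
#' @param duration numeric vector of frame durations (minutes), all positive.
#'   Frames must not overlap: \code{start[i] + duration[i] <= start[i+1]}.
#' @return An object of class \code{frame_schedule}.
#' @examples
#' sch <- frame_schedule(start = c(0, 1, 2), duration = c(1, 1, 2))
#' frame_mid(sch)
#' @export
frame_schedule <- function(start, duration) {
  start <- as.numeric(start); duration <- as.numeric(duration)
  if (length(start) != length(duration) || length(start) == 0L)
    stop("'start' and 'duration' must be nonempty vectors of equal length")
  if (any(!is.finite(start)) || any(!is.finite(duration)))
    stop("frame times must be finite")
  if (any(duration <= 0)) stop("all frame durations must be > 0")
  if (length(start) > 1L) {
    if (any(diff(start) <= 0)) stop("frame starts must be strictly increasing")
    if (any(start[-length(start)] + duration[-length(duration)] >
            start[-1L] + 1e-9))
      stop("frames must not overlap")
  }
  structure(list(start = start, duration = duration),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start)

#' Frame mid-times and end-times
#'
#' @param schedule a \code{frame_schedule}.
#' @return Numeric vector in minutes.
#' @export
frame_mid <- function(schedule) schedule$start + schedule$duration / 2

#' @rdname frame_mid
#' @export
frame_end <- function(schedule) schedule$start + schedule$duration

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.2f-%.2f min\n",
              length(x$start), x$start[1], max(frame_end(x))))
  invisible(x)
}

#' Time-activity curve
#'
#' A time-activity curve (TAC) holds one activity-concentration value per
#' frame (kBq/mL) together with its decay-correction state.  Decay-corrected
#' curves must record the reference time the correction refers to, on the
#' study clock.
#'
#' @param schedule a \code{frame_schedule}.
#' @param values numeric vector, one finite value per frame, kBq/mL.
#' @param region region label.
#' @param decay_corrected logical; is the curve decay corrected?
#' @param decay_reference reference time of the decay correction (minutes on
#'   the study clock); required when \code{decay_corrected} is \code{TRUE}.
#' @return An object of class \code{tac}.
#' @seealso [decay_correct()], [frame_average()]
#' @export
tac <- function(schedule, values, region = "region",
                decay_corrected = FALSE, decay_reference = NULL) {
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule")
  values <- as.numeric(values)
  if (length(values) != length(schedule$start))
    stop("'values' must have one entry per frame")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  if (isTRUE(decay_corrected)) {
    if (is.null(decay_reference))
      stop("'decay_reference' is required for a decay-corrected curve")
    stopifnot_scalar(decay_reference, "decay_reference")
  } else decay_reference <- NULL
  structure(list(schedule = schedule, values = values,
                 region = as.character(region),
                 decay_corrected = isTRUE(decay_corrected),
                 decay_reference = decay_reference),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC '%s': %d frames, %.2f-%.2f min, %s\n", x$region,
              length(x$values), x$schedule$start[1],
              max(frame_end(x$schedule)),
              if (x$decay_corrected)
                sprintf("decay-corrected (ref %.1f min)", x$decay_reference)
              else "not decay-corrected"))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(frame_start_min = x$schedule$start,
             frame_end_min = frame_end(x$schedule),
             region = x$region,
             value_kBq_per_mL = x$values)
}

#' Injection event
#'
#' @param tracer tracer name.
#' @param activity_MBq injected activity in MBq (> 0).
#' @param time_min injection time in minutes on the study clock.
#' @param half_life_min isotope half-life in minutes (default: physical
#'   half-life of 18F, 109.77 min).
#' @return An object of class \code{injection_event}.
#' @export
injection_event <- function(tracer, activity_MBq, time_min = 0,
                            half_life_min = HALF_LIFE_18F) {
  stopifnot_scalar(activity_MBq, "activity_MBq", positive = TRUE)
  stopifnot_scalar(time_min, "time_min")
  stopifnot_scalar(half_life_min, "half_life_min", positive = TRUE)
  structure(list(tracer = as.character(tracer),
                 activity_MBq = activity_MBq, time_min = time_min,
                 half_life_min = half_life_min),
            class = "injection_event")
}

#' Apply or remove radioactive decay correction
#'
#' Multiplies each frame value by \code{exp(+/- lambda * (t_mid - reference))}
#' with \code{lambda = log(2) / half_life}, using frame mid-times, and flips
#' the curve's decay-correction flag.  Applying a correction to an already
#' corrected curve (or removing one twice) is an error: the state flag makes
#' double application impossible.
#'
#' @param curve a \code{tac}.
#' @param half_life isotope half-life in minutes.
#' @param reference_time reference time of the correction, minutes on the
#'   study clock.
#' @param direction \code{"apply"} (curve must be uncorrected) or
#'   \code{"remove"} (curve must be corrected).
#' @return The corrected/uncorrected \code{tac}.
#' @examples
#' sch <- frame_schedule(0:3, rep(1, 4))
#' x <- tac(sch, c(4, 3, 2, 1))
#' y <- decay_correct(x, 109.77, 0, "apply")
#' z <- decay_correct(y, 109.77, 0, "remove")
#' all.equal(z$values, x$values)
#' @export
decay_correct <- function(curve, half_life, reference_time,
                          direction = c("apply", "remove")) {
  direction <- match.arg(direction)
  if (!inherits(curve, "tac")) stop("'curve' must be a tac")
  stopifnot_scalar(half_life, "half_life", positive = TRUE)
  stopifnot_scalar(reference_time, "reference_time")
  if (direction == "remove" && !curve$decay_corrected)
    stop("cannot remove decay correction: curve is not decay-corrected")
  if (direction == "apply" && curve$decay_corrected)
    stop("cannot apply decay correction twice")
  lambda <- log(2) / half_life
  tm <- frame_mid(curve$schedule)
  fac <- exp(lambda * (tm - reference_time))
  if (direction == "remove") fac <- 1 / fac
  tac(curve$schedule, curve$values * fac, region = curve$region,
      decay_corrected = direction == "apply",
      decay_reference = if (direction == "apply") reference_time else NULL)
}

#' Average a continuous model over the frames of a schedule
#'
#' Each frame value is the mean of the continuous curve over the frame
#' interval, computed by trapezoidal quadrature on a fine regular grid.
#'
#' @param f a function of time (minutes) returning concentration (kBq/mL);
#'   must be defined over every frame interval.
#' @param schedule a \code{frame_schedule}.
#' @param dt quadrature step in minutes.
#' @param ... passed to \code{tac()} (region, decay state).
#' @return A \code{tac} on \code{schedule}.
#' @export
frame_average <- function(f, schedule, dt = 1 / 120, ...) {
  if (!is.function(f)) stop("'f' must be a function of time")
  vals <- vapply(seq_along(schedule$start), function(i) {
    a <- schedule$start[i]; b <- a + schedule$duration[i]
    n <- max(2L, ceiling((b - a) / dt) + 1L)
    tt <- seq(a, b, length.out = n)
    y <- f(tt)
    if (any(!is.finite(y)))
      stop(sprintf("model not defined over frame [%g, %g]", a, b))
    sum(diff(tt) * (y[-1] + y[-n]) / 2) / (b - a)
  }, numeric(1))
  tac(schedule, vals, ...)
}

#' Standardized uptake value per frame
#'
#' SUV = concentration (kBq/mL) * body weight (kg) / injected activity (MBq),
#' assuming a tissue density of 1 g/mL.  The curve must be decay-corrected to
#' the injection time of \code{injection}.
#'
#' @param curve a decay-corrected \code{tac} (kBq/mL).
#' @param injection an \code{injection_event} (MBq).
#' @param body_weight body weight in kg (> 0).
#' @return Numeric vector of unitless SUVs, one per frame.
#' @examples
#' sch <- frame_schedule(0, 5)
#' x <- tac(sch, 12.5, decay_corrected = TRUE, decay_reference = 0)
#' compute_suv(x, injection_event("FDG", 394, 0), 93.5)
#' @export
compute_suv <- function(curve, injection, body_weight) {
  if (!inherits(curve, "tac")) stop("'curve' must be a tac")
  if (!inherits(injection, "injection_event"))
    stop("'injection' must be an injection_event")
  stopifnot_scalar(body_weight, "body_weight", positive = TRUE)
  if (!curve$decay_corrected)
    stop("SUV requires a decay-corrected curve")
  if (abs(curve$decay_reference - injection$time_min) > 1e-6)
    stop("curve must be decay-corrected to the injection time")
  # kBq/mL divided by (MBq * 1000 / (kg * 1000)) kBq/g, density 1 g/mL
  curve$values * body_weight / injection$activity_MBq
}

#' Read and write TAC tables as CSV
#'
#' The CSV carries columns \code{frame_start_min, frame_end_min, region,
#' value_kBq_per_mL}; leading comment lines (\code{#}) record the decay
#' state (\code{decay_corrected}, \code{decay_reference_min}) and units.
#'
#' @param file path.
#' @param curves a named list of \code{tac} objects sharing one schedule.
#' @return \code{read_tac_csv} returns a named list of \code{tac} objects.
#' @export
write_tac_csv <- function(curves, file) {
  if (inherits(curves, "tac")) curves <- list(curves)
  stopifnot(length(curves) > 0)
  c1 <- curves[[1]]
  hdr <- c("# units: minutes, kBq/mL",
           sprintf("# decay_corrected: %s",
                   tolower(as.character(c1$decay_corrected))),
           if (c1$decay_corrected)
             sprintf("# decay_reference_min: %g", c1$decay_reference))
  df <- do.call(rbind, lapply(curves, as.data.frame))
  con <- file(file, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (length(m)) trimws(sub(".*:", "", m[1])) else NULL
  }
  dc <- identical(getv("decay_corrected"), "true")
  ref <- getv("decay_reference_min")
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  need <- c("frame_start_min", "frame_end_min", "region", "value_kBq_per_mL")
  if (!all(need %in% names(df)))
    stop("TAC CSV must have columns ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$frame_start_min), ]
    tac(frame_schedule(d$frame_start_min,
                       d$frame_end_min - d$frame_start_min),
        d$value_kBq_per_mL, region = d$region[1],
        decay_corrected = dc,
        decay_reference = if (dc) as.numeric(ref))
  })
  out[unique(df$region)]
}
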