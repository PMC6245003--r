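#' Zero-phase low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter forward and backward
#' (zero-phase, so symmetric pulses keep their peak sample and the effective
#' amplitude response is the squared one-pass magnitude: 0.5 at the cutoff
#' for any order). Marker data are conventionally filtered at 6 Hz with a
#' second-order bidirectional filter, which these defaults reproduce.
#'
#' End transients are suppressed by odd (reflect-and-negate) extension of
#' `3 * ceiling(fs / fc)` samples at each end before filtering.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate (Hz); must exceed `2 * fc`.
#' @param fc cutoff frequency (Hz), default 6.
#' @param order filter order, default 2.
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, fc = 6, order = 2) {
  if (is.matrix(x)) {
    return(apply(x, 2L, lowpass_filter, fs = fs, fc = fc, order = order))
  }
  if (fs <= 2 * fc) gs_stop("validation", "fs must exceed 2 * fc")
  n <- length(x)
  if (n <= 6L * order) {
    gs_stop("too_short",
            sprintf("series of length %d too short to filter (need > %d)",
                    n, 6L * order))
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  pad <- min(3L * as.integer(ceiling(fs / fc)), n - 1L)
  front <- 2 * x[1L] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(pad + 1L):(pad + n)]
}

#' Detect heel strikes from heel-to-pelvis excursion
#'
#' Heel-strike events are the local maxima of the anterior-posterior position
#' of each heel marker relative to the pelvis: at heel strike the foot is at
#' its most forward position with respect to the body. Both channels are
#' low-pass filtered (see [lowpass_filter()]) before peak picking, peaks are
#' constrained by a minimum separation and a minimum prominence, and the two
#' feet's events are merged into a strictly alternating sequence (when two
#' same-side events are adjacent, the less prominent one is dropped).
#'
#' @param trial a [gait_trial()].
#' @param min_separation_s minimum time between same-foot peaks (s). The
#'   default 0.35 s is about 0.65 of a typical 0.55 s step time.
#' @param min_prominence_m minimum peak prominence (m).
#' @param fc filter cutoff passed to [lowpass_filter()]; `NULL` skips
#'   filtering.
#' @return object of class `gait_events`: a data.frame with columns `sample`
#'   (1-based), `time` (s), `side` ("L"/"R") and `dominant` (logical),
#'   carrying attributes `fs` and `dominant_side`.
#' @export
detect_heel_strikes <- function(trial, min_separation_s = 0.35,
                                min_prominence_m = 0.01, fc = 6) {
  fs <- trial$fs
  pelvis_ap <- trial$markers$pelvis[, "y"]
  if (!is.null(fc)) pelvis_ap <- lowpass_filter(pelvis_ap, fs, fc)
  per_side <- lapply(c(L = "L", R = "R"), function(side) {
    heel_ap <- trial$markers[[paste0("heel_", side)]][, "y"]
    if (!is.null(fc)) heel_ap <- lowpass_filter(heel_ap, fs, fc)
    rel <- heel_ap - pelvis_ap
    pk <- find_peaks(rel,
                     min_distance = as.integer(round(min_separation_s * fs)),
                     min_prominence = min_prominence_m)
    if (nrow(pk)) pk$side <- side
    pk
  })
  if (nrow(per_side$L) < 2L || nrow(per_side$R) < 2L) {
    gs_stop("no_gait", "fewer than 2 heel strikes detected on one side")
  }
  ev <- rbind(per_side$L, per_side$R)
  ev <- ev[order(ev$sample), ]
  # enforce strict L/R alternation: in any same-side run keep the most
  # prominent event
  repeat {
    same <- which(ev$side[-1L] == ev$side[-nrow(ev)])
    if (!length(same)) break
    i <- same[1L]
    drop <- if (ev$prominence[i] >= ev$prominence[i + 1L]) i + 1L else i
    ev <- ev[-drop, ]
  }
  gait_events(ev$sample, ev$side, trial)
}

#' Build a gait-events object from known heel-strike samples
#'
#' @param samples 1-based heel-strike sample indices, strictly increasing.
#' @param sides character vector of "L"/"R", strictly alternating.
#' @param trial the trial the events belong to (for `fs` and dominance).
#' @return a `gait_events` data.frame; see [detect_heel_strikes()].
#' @export
gait_events <- function(samples, sides, trial) {
  if (length(samples) != length(sides)) {
    gs_stop("validation", "samples and sides must have equal length")
  }
  if (is.unsorted(samples, strictly = TRUE)) {
    gs_stop("validation", "heel-strike samples must be strictly increasing")
  }
  if (length(sides) >= 2L && any(sides[-1L] == sides[-length(sides)])) {
    gs_stop("validation", "heel-strike sides must alternate")
  }
  n <- length(trial$t)
  if (any(samples < 1L | samples > n)) {
    gs_stop("validation", "heel-strike sample outside trial")
  }
  dom <- trial$meta$dominant_side
  ev <- data.frame(
    sample = as.integer(samples),
    time = trial$t[samples],
    side = sides,
    dominant = sides == dom,
    stringsAsFactors = FALSE
  )
  structure(ev, class = c("gait_events", "data.frame"),
            fs = trial$fs, dominant_side = dom)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d heel strikes (%d L, %d R), dominant side %s\n",
              nrow(x), sum(x$side == "L"), sum(x$side == "R"),
              attr(x, "dominant_side")))
  invisible(x)
}

#' Number of complete strides per side
#'
#' A stride spans consecutive heel strikes of the same foot.
#'
#' @param events a `gait_events` object.
#' @return named integer vector with elements `L` and `R`.
#' @export
stride_count <- function(events) {
  c(L = max(0L, sum(events$side == "L") - 1L),
    R = max(0L, sum(events$side == "R") - 1L))
}

#' Segment heel strikes into steps
#'
#' A step spans two consecutive heel strikes of opposite feet and is labelled
#' by the side of the terminating strike. N heel strikes yield N - 1 steps.
#'
#' @param events a `gait_events` object.
#' @return data.frame with columns `step_index`, `start_sample`,
#'   `end_sample`, `side` (terminating side).
#' @export
segment_steps <- function(events) {
  if (nrow(events) < 2L) gs_stop("no_gait", "need at least 2 heel strikes")
  n <- nrow(events)
  data.frame(
    step_index = seq_len(n - 1L),
    start_sample = events$sample[-n],
    end_sample = events$sample[-1L],
    side = events$side[-1L],
    stringsAsFactors = FALSE
  )
}
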