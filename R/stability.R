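#' Inverted-pendulum parameters for the extrapolated centre of mass
#'
#' The extrapolated centre of mass (XCoM) corrects the CoM position by its
#' velocity scaled with the inverted-pendulum eigenfrequency
#' `omega0 = sqrt(g / l)`. The pendulum length `l` is taken as 1.34 times the
#' average height of the two greater-trochanter markers.
#'
#' @param l pendulum length (m). If `NULL`, computed from `trial` as
#'   1.34 times the time-average of the two trochanter markers' vertical
#'   position.
#' @param g gravitational acceleration (m/s^2), fixed at 9.81 by default.
#' @param trial optional [gait_trial()] used to derive `l`.
#' @return list of class `xcom_params` with elements `g`, `l`, `omega0`.
#' @export
xcom_params <- function(l = NULL, g = 9.81, trial = NULL) {
  if (is.null(l)) {
    if (is.null(trial)) {
      gs_stop("validation", "supply either l or a trial to derive it from")
    }
    troch_z <- c(trial$markers$trochanter_L[, "z"],
                 trial$markers$trochanter_R[, "z"])
    l <- 1.34 * mean(troch_z)
  }
  if (!is.finite(l) || l <= 0) gs_stop("validation", "pendulum length must be > 0")
  structure(list(g = g, l = l, omega0 = sqrt(g / l)), class = "xcom_params")
}

#' @export
print.xcom_params <- function(x, ...) {
  cat(sprintf("<xcom_params> l = %.3f m, g = %.2f m/s^2, omega0 = %.4f 1/s\n",
              x$l, x$g, x$omega0))
  invisible(x)
}

#' Extrapolated centre of mass
#'
#' `XCoM = CoM + v / omega0` per horizontal axis, with
#' `omega0 = sqrt(g / l)`.
#'
#' @param com_position n-by-3 (or n-by-2) CoM position matrix; the first two
#'   columns are taken as ML and AP.
#' @param com_velocity matrix of matching size with the CoM velocity.
#' @param params an [xcom_params()] object.
#' @return n-by-2 matrix with columns `ml`, `ap`.
#' @export
compute_xcom <- function(com_position, com_velocity, params) {
  if (nrow(com_position) != nrow(com_velocity)) {
    gs_stop("validation", "position and velocity must have equal length")
  }
  p <- com_position[, 1:2, drop = FALSE]
  v <- com_velocity[, 1:2, drop = FALSE]
  if (!all(is.finite(p)) || !all(is.finite(v))) {
    gs_stop("non_finite", "non-finite values in CoM position or velocity")
  }
  x <- p + v / params$omega0
  colnames(x) <- c("ml", "ap")
  x
}

#' Centre-of-mass velocity in the belt or lab frame
#'
#' Central-difference derivative of the CoM position. On a treadmill the
#' lab-frame AP CoM velocity averages near zero; in the default belt frame
#' the speed of the stance-side belt (the belt under the foot that made the
#' most recent heel strike) is added to the AP component at every sample, so
#' the velocity reflects progression relative to the moving surface.
#'
#' @param trial a [gait_trial()].
#' @param frame `"belt"` (default) or `"lab"`.
#' @param events optional `gait_events`; detected internally when `NULL` and
#'   `frame = "belt"`.
#' @param filter logical; low-pass filter the CoM position first.
#' @return n-by-3 velocity matrix (columns x = ML, y = AP, z = VT).
#' @export
com_velocity <- function(trial, frame = c("belt", "lab"), events = NULL,
                         filter = TRUE) {
  frame <- match.arg(frame)
  com <- trial$com
  if (filter) com <- lowpass_filter(com, trial$fs)
  v <- apply(com, 2L, central_diff, fs = trial$fs)
  colnames(v) <- TRIAL_AXES
  if (frame == "belt") {
    if (is.null(events)) events <- detect_heel_strikes(trial)
    v[, "y"] <- v[, "y"] + stance_belt_speed(trial, events)
  }
  v
}

# Belt speed of the stance foot (the foot with the most recent heel strike)
# at every sample; before the first strike, the opposite foot of the first
# event is assumed to be in stance.
stance_belt_speed <- function(trial, events) {
  n <- length(trial$t)
  idx <- findInterval(seq_len(n), events$sample)
  side <- ifelse(idx == 0L,
                 ifelse(events$side[1L] == "L", "R", "L"),
                 events$side[pmax(idx, 1L)])
  ifelse(side == "L", trial$belt_speed_L, trial$belt_speed_R)
}

#' Per-step margins of stability
#'
#' Evaluates the medio-lateral and anterior-posterior margins of stability
#' (MoS) at each heel-strike sample, with the striking (leading) foot
#' defining the border of the base of support: the lateral malleolus marker
#' gives the ML border, the heel marker the backward AP border.
#'
#' Sign conventions: `mos_ml = d_s * (malleolus_ML - XCoM_ML)` with `d_s = +1`
#' for a right and `-1` for a left leading foot, so positive means the
#' malleolus lies lateral to the XCoM; `mos_ap = XCoM_AP - heel_AP`, so
#' positive means the heel lands behind the XCoM. Negative values indicate
#' instability laterally / backward.
#'
#' @param trial a [gait_trial()].
#' @param events a `gait_events` object.
#' @param params an [xcom_params()]; derived from the trial when `NULL`.
#' @param frame velocity frame passed to [com_velocity()].
#' @param filter logical; low-pass filter markers and CoM (default TRUE).
#'   Disable for noise-free data where filtering is unnecessary.
#' @return data.frame with one row per heel strike: `sample`, `side`,
#'   `mos_ml`, `mos_ap`.
#' @export
compute_step_mos <- function(trial, events, params = NULL,
                             frame = c("belt", "lab"), filter = TRUE) {
  frame <- match.arg(frame)
  if (is.null(params)) params <- xcom_params(trial = trial)
  need <- c("malleolus_L", "malleolus_R", "heel_L", "heel_R")
  if (!all(need %in% names(trial$markers))) {
    gs_stop("missing_channel", "malleolus/heel markers required for MoS")
  }
  v <- com_velocity(trial, frame = frame, events = events, filter = filter)
  com <- if (filter) lowpass_filter(trial$com, trial$fs) else trial$com
  xcom <- compute_xcom(com, v, params)
  mk <- trial$markers[need]
  if (filter) mk <- lapply(mk, lowpass_filter, fs = trial$fs)
  i <- events$sample
  lead_is_R <- events$side == "R"
  mall_ml <- ifelse(lead_is_R, mk$malleolus_R[i, "x"], mk$malleolus_L[i, "x"])
  heel_ap <- ifelse(lead_is_R, mk$heel_R[i, "y"], mk$heel_L[i, "y"])
  d_s <- ifelse(lead_is_R, 1, -1)
  data.frame(
    sample = i,
    side = events$side,
    mos_ml = d_s * (mall_ml - xcom[i, "ml"]),
    mos_ap = xcom[i, "ap"] - heel_ap,
    stringsAsFactors = FALSE
  )
}

#' Spatio-temporal step parameters
#'
#' Step time, step length and step width are the elapsed time, AP distance
#' and absolute ML distance between two consecutive heel strikes. Distances
#' are measured between the two heel markers at the instant of the later
#' (terminating) heel strike, the standard treadmill convention: the
#' between-event lab-frame displacement would be confounded by the belt.
#'
#' @inheritParams compute_step_mos
#' @return data.frame with one row per step (N - 1 rows for N strikes):
#'   `step_index`, `side` (terminating side), `hs_sample` (terminating
#'   strike), `step_time` (s), `step_length` (m), `step_width` (m).
#' @export
spatiotemporal <- function(trial, events, filter = TRUE) {
  if (nrow(events) < 2L) gs_stop("no_gait", "need at least 2 heel strikes")
  heel <- trial$markers[c("heel_L", "heel_R")]
  if (filter) heel <- lapply(heel, lowpass_filter, fs = trial$fs)
  n <- nrow(events)
  new_i <- events$sample[-1L]
  new_side <- events$side[-1L]
  old_side <- events$side[-n]
  pick <- function(side, i, ax) {
    ifelse(side == "R", heel$heel_R[i, ax], heel$heel_L[i, ax])
  }
  data.frame(
    step_index = seq_len(n - 1L),
    side = new_side,
    hs_sample = new_i,
    step_time = diff(events$time),
    step_length = pick(new_side, new_i, "y") - pick(old_side, new_i, "y"),
    step_width = abs(pick(new_side, new_i, "x") - pick(old_side, new_i, "x")),
    stringsAsFactors = FALSE
  )
}

#' Full per-step record table
#'
#' Combines [spatiotemporal()] and [compute_step_mos()] into one tidy table
#' with one row per step; the MoS pair of a step is the one evaluated at its
#' terminating heel strike.
#'
#' @inheritParams compute_step_mos
#' @return data.frame with columns `step_index`, `side`, `hs_sample`,
#'   `step_time`, `step_length`, `step_width`, `mos_ml`, `mos_ap` and
#'   `dominant` (logical).
#' @export
step_table <- function(trial, events, params = NULL,
                       frame = c("belt", "lab"), filter = TRUE) {
  frame <- match.arg(frame)
  st <- spatiotemporal(trial, events, filter = filter)
  mos <- compute_step_mos(trial, events, params = params, frame = frame,
                          filter = filter)
  st$mos_ml <- mos$mos_ml[-1L]
  st$mos_ap <- mos$mos_ap[-1L]
  st$dominant <- st$side == attr(events, "dominant_side")
  st
}

#' Baseline summary over a fixed number of steps per side
#'
#' Averages each gait parameter over `n_per_side` consecutive dominant (BD)
#' and non-dominant (BND) steps, after skipping an initial warm-up.
#'
#' @param steps a step table from [step_table()] (must carry `dominant`).
#' @param n_per_side steps per side entering the summary (default 100).
#' @param skip_strides warm-up strides discarded at the start (default 5).
#' @param parameters gait parameters to summarize.
#' @return object of class `baseline_summary`: data.frame with columns
#'   `parameter`, `side_role` ("D"/"ND"), `mean`, `sd`, `n`.
#' @export
baseline_summary <- function(steps, n_per_side = 100, skip_strides = 5,
                             parameters = GAIT_PARAMETERS) {
  stopifnot(all(parameters %in% names(steps)))
  use <- steps[-seq_len(min(nrow(steps), 2L * skip_strides)), , drop = FALSE]
  out <- list()
  for (role in c(D = TRUE, ND = FALSE)) {
    sel <- use[use$dominant == role, , drop = FALSE]
    if (nrow(sel) < n_per_side) {
      gs_stop("insufficient_baseline", sprintf(
        "only %d %s steps available after warm-up; %d required",
        nrow(sel), if (role) "dominant" else "non-dominant", n_per_side))
    }
    sel <- sel[seq_len(n_per_side), , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      parameter = parameters,
      side_role = if (role) "D" else "ND",
      mean = vapply(parameters, function(p) mean(sel[[p]]), numeric(1)),
      sd = vapply(parameters, function(p) stats::sd(sel[[p]]), numeric(1)),
      n = n_per_side,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  structure(do.call(rbind, out),
            class = c("baseline_summary", "data.frame"),
            n_per_side = n_per_side)
}

baseline_mean <- function(baseline, parameter, role) {
  baseline$mean[baseline$parameter == parameter & baseline$side_role == role]
}
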