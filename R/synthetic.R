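#' Parameters of the synthetic treadmill-walking generator
#'
#' The generator produces a kinematic template of steady dual-belt treadmill
#' walking (no dynamics or balance control): alternating heel strikes at a
#' fixed step time, heels carried backward at belt speed during stance and
#' swung forward along smooth quintic trajectories, a CoM that sways
#' medio-laterally at stride frequency and oscillates vertically twice per
#' stride. Defaults correspond to a comfortable walking speed of 1.2 m/s
#' with 0.55 s steps of 0.68 m length and 0.12 m width, typical adult
#' treadmill values.
#'
#' @param comfortable_speed belt speed (m/s).
#' @param step_time programmed step time (s).
#' @param step_length programmed step length (m).
#' @param step_width programmed step width (m).
#' @param com_sway_amp ML CoM sway amplitude (m).
#' @param trunk_noise_sd white-noise SD added to the trunk marker (m).
#' @param marker_noise_sd white-noise SD added to every marker (m).
#' @param dominant_side "L" or "R".
#' @param duration trial duration (s); must be at least 10 step times.
#' @param fs sampling rate (Hz).
#' @param seed RNG seed used for any noise (and nothing else).
#' @param heel_lead AP distance from the CoM to the leading heel at strike
#'   (m); sets the baseline AP margin of stability.
#' @param stance_fraction fraction of a stride a foot spends in stance.
#' @param contact_tau duration of the smooth stance-entry velocity blend (s).
#' @param swing_lift peak heel lift during swing (m).
#' @param ap_osc_amp amplitude of the CoM AP oscillation (m).
#' @param vt_osc_amp amplitude of the CoM vertical oscillation (m).
#' @param troch_height trochanter marker height (m); the pendulum length of
#'   the stability model is 1.34 times this.
#' @return validated list of class `gait_params`.
#' @export
gait_params <- function(comfortable_speed = 1.2, step_time = 0.55,
                        step_length = 0.68, step_width = 0.12,
                        com_sway_amp = 0.02, trunk_noise_sd = 0,
                        marker_noise_sd = 0, dominant_side = "R",
                        duration = 120, fs = 100, seed = 1L,
                        heel_lead = 0.29, stance_fraction = 0.6,
                        contact_tau = 0.05, swing_lift = 0.06,
                        ap_osc_amp = 0.005, vt_osc_amp = 0.015,
                        troch_height = 1.0) {
  p <- as.list(environment())
  pos <- c("comfortable_speed", "step_time", "step_length", "step_width",
           "duration", "fs", "heel_lead", "stance_fraction", "contact_tau",
           "swing_lift", "troch_height")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      gs_stop("validation", paste(nm, "must be positive"))
    }
  }
  if (!dominant_side %in% c("L", "R")) {
    gs_stop("validation", "dominant_side must be 'L' or 'R'")
  }
  if (duration < 10 * step_time) {
    gs_stop("validation", "duration must be at least 10 step times")
  }
  if (com_sway_amp < 0 || trunk_noise_sd < 0 || marker_noise_sd < 0) {
    gs_stop("validation", "amplitudes and noise SDs must be non-negative")
  }
  structure(p, class = "gait_params")
}

#' Perturbation profile specification
#'
#' Builds the parameter set of one of the six perturbation types, with
#' defaults matching the protocol this package models: a 5 cm platform
#' translation in about 0.7 s (peak acceleration 2.04 m/s^2) toward the
#' non-dominant (ipsilateral) or dominant (contralateral) side; a unilateral
#' non-dominant belt acceleration to 160% or deceleration to 40% of the
#' comfortable speed over about 0.4 s; a 5 s visual blackout (< 1 lx); or a
#' 0.5 s, 82 dB auditory startle. Sensory perturbations carry no kinematic
#' profile.
#'
#' @param ptype one of `sway_ipsi`, `sway_contra`, `belt_acc`, `belt_dec`,
#'   `visual`, `auditory`.
#' @param ... overrides of the profile parameters: for sway
#'   `displacement` (m), `duration` (s), `a_max` (m/s^2),
#'   `return_to_center` (logical), `return_delay` (s), `return_duration`
#'   (s); for belt `factor`, `ramp` (s), `hold` (s); for visual
#'   `duration` (s), `lux`; for auditory `duration` (s), `level_db`.
#' @return list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(ptype, ...) {
  ptype <- match.arg(ptype, PERTURBATION_TYPES)
  defaults <- switch(
    ptype,
    sway_ipsi = ,
    sway_contra = list(displacement = 0.05, duration = 0.7, a_max = 2.04,
                       return_to_center = TRUE, return_delay = 4.0,
                       return_duration = 3.0),
    belt_acc = list(factor = 1.6, ramp = 0.4, hold = NA_real_),
    belt_dec = list(factor = 0.4, ramp = 0.4, hold = NA_real_),
    visual = list(duration = 5, lux = 1),
    auditory = list(duration = 0.5, level_db = 82)
  )
  spec <- utils::modifyList(defaults, list(...))
  if (grepl("^sway", ptype)) {
    if (spec$displacement > spec$a_max * (spec$duration / 2)^2) {
      gs_stop("infeasible_profile",
              "trapezoidal profile unsolvable: d > a_max * (T/2)^2")
    }
  }
  structure(c(list(ptype = ptype), spec), class = "perturbation_spec")
}

#' Scripted recovery response
#'
#' Additive deviations applied to the six post-perturbation steps of an
#' injected perturbation, as data: per step a step-time deviation `d_time`
#' (s), an AP foot-placement deviation `d_ap` (m, positive = landing further
#' ahead, which lengthens that step and reduces its AP margin of stability)
#' and an ML deviation `d_ml` (m, positive = landing further lateral, which
#' widens that step and increases its ML margin of stability).
#'
#' @param d_time,d_ap,d_ml numeric length-6 vectors (recycled from scalars).
#' @return list of class `response_script` with three length-6 vectors.
#' @export
response_script <- function(d_time = 0, d_ap = 0, d_ml = 0) {
  fix <- function(x) {
    x <- rep_len(as.numeric(x), 6L)
    if (any(!is.finite(x))) gs_stop("validation", "script deviations must be finite")
    x
  }
  structure(list(d_time = fix(d_time), d_ap = fix(d_ap), d_ml = fix(d_ml)),
            class = "response_script")
}

#' Default recovery script per perturbation type
#'
#' Templates qualitatively mimicking the typical recovery courses reported
#' for each perturbation type: a narrow (cross-) first step followed by
#' faster, shorter, wider steps after a contralateral sway; backward
#' instability followed by shorter, faster, wider steps after a belt
#' deceleration; milder responses to ipsilateral sway and belt acceleration;
#' no kinematic response to the sensory perturbations. Deviations decay to
#' baseline by the sixth step.
#'
#' @param ptype perturbation type.
#' @return a [response_script()].
#' @export
default_script <- function(ptype) {
  ptype <- match.arg(ptype, PERTURBATION_TYPES)
  switch(
    ptype,
    sway_ipsi = response_script(
      d_time = c(0, -0.01, 0, 0, 0, 0),
      d_ap = c(0, -0.01, -0.01, 0, 0, 0),
      d_ml = c(0.03, 0.02, 0.01, 0, 0, 0)
    ),
    sway_contra = response_script(
      d_time = c(0, -0.03, -0.04, -0.03, -0.02, -0.01),
      d_ap = c(0, -0.05, -0.05, -0.04, -0.02, -0.01),
      d_ml = c(-0.08, -0.02, 0.04, 0.01, 0.005, 0)
    ),
    belt_acc = response_script(
      d_time = c(-0.02, -0.01, 0, 0, 0, 0),
      d_ap = c(0.20, 0.10, -0.15, -0.10, -0.04, -0.01),
      d_ml = c(0.01, 0.01, 0, 0, 0, 0)
    ),
    belt_dec = response_script(
      d_time = c(0.02, -0.03, -0.04, -0.03, -0.01, 0),
      d_ap = c(0, 0.05, -0.02, -0.02, -0.01, 0),
      d_ml = c(0.02, 0.02, 0.02, 0.01, 0.01, 0)
    ),
    visual = response_script(),
    auditory = response_script()
  )
}

#' Medio-lateral platform sway profile
#'
#' Trapezoidal-velocity translation: accelerate at `a_max` for `t_a`, coast,
#' decelerate at `a_max`, where `t_a` is the smaller root of
#' `a_max * t_a * (T - t_a) = d`. The net displacement is exactly
#' `d * direction` with zero start and end velocity.
#'
#' @param displacement net displacement d (m).
#' @param duration profile duration T (s).
#' @param a_max peak acceleration (m/s^2).
#' @param direction +1 or -1.
#' @param fs sampling rate (Hz).
#' @return numeric displacement series of length `round(duration * fs) + 1`.
#' @export
make_platform_profile <- function(displacement = 0.05, duration = 0.7,
                                  a_max = 2.04, direction = 1, fs = 100) {
  f <- sway_profile_funs(displacement, duration, a_max, direction)
  t <- seq(0, duration, by = 1 / fs)
  f$pos(t)
}

# Analytic position/velocity closures for the trapezoidal sway profile.
sway_profile_funs <- function(d, T, a_max, direction) {
  disc <- T^2 - 4 * d / a_max
  if (disc < 0) {
    gs_stop("infeasible_profile",
            "trapezoidal profile unsolvable: d > a_max * (T/2)^2")
  }
  t_a <- (T - sqrt(disc)) / 2
  v_p <- a_max * t_a
  pos1 <- function(t) {  # unsigned position
    ifelse(t <= 0, 0,
    ifelse(t < t_a, 0.5 * a_max * t^2,
    ifelse(t < T - t_a, 0.5 * a_max * t_a^2 + v_p * (t - t_a),
    ifelse(t < T, d - 0.5 * a_max * (T - t)^2, d))))
  }
  vel1 <- function(t) {
    ifelse(t <= 0 | t >= T, 0,
    ifelse(t < t_a, a_max * t,
    ifelse(t < T - t_a, v_p, a_max * (T - t))))
  }
  list(pos = function(t) direction * pos1(t),
       vel = function(t) direction * vel1(t),
       t_a = t_a, v_peak = v_p, duration = T)
}

# Min-jerk return-to-centre segment: displacement `delta` over `T_r`.
minjerk_move_funs <- function(delta, T_r) {
  list(
    pos = function(t) delta * minjerk_s(t / T_r),
    vel = function(t) {
      s <- t / T_r
      ifelse(s <= 0 | s >= 1, 0,
             delta * (30 * s^2 - 60 * s^3 + 30 * s^4) / T_r)
    }
  )
}

#' Unilateral belt-speed perturbation profile
#'
#' Minimum-jerk speed ramp from `v_c` to `factor * v_c` over `ramp` seconds,
#' hold for `hold` seconds (one step time by default), minimum-jerk return.
#' The extremum speed is exactly `factor * v_c` and the peak belt
#' acceleration is `1.875 * |factor - 1| * v_c / ramp`, the minimum-jerk
#' peak-rate constant.
#'
#' @param v_c comfortable speed (m/s).
#' @param factor speed factor (1.6 for the standard acceleration, 0.4 for
#'   the deceleration).
#' @param ramp ramp time (s).
#' @param hold hold time at the extremum (s).
#' @param fs sampling rate (Hz).
#' @return numeric speed series of length `round((2*ramp+hold)*fs) + 1`.
#' @export
make_belt_profile <- function(v_c, factor = 1.6, ramp = 0.4, hold = 0.55,
                              fs = 100) {
  if (factor <= 0) gs_stop("validation", "factor must be > 0")
  f <- belt_profile_fun(v_c, factor, ramp, hold)
  t <- seq(0, 2 * ramp + hold, by = 1 / fs)
  f(t)
}

# Analytic belt-speed closure; returns v_c outside the profile support.
belt_profile_fun <- function(v_c, factor, ramp, hold) {
  dv <- (factor - 1) * v_c
  function(t) {
    ifelse(t <= 0 | t >= 2 * ramp + hold, v_c,
    ifelse(t < ramp, v_c + dv * minjerk_s(t / ramp),
    ifelse(t < ramp + hold, v_c + dv,
           v_c + dv * minjerk_s((2 * ramp + hold - t) / ramp))))
  }
}

# Solve the steady-state lab-frame drift speed of the template. During
# stance the heel tracks the belt except for a smooth entry blend whose
# extra forward displacement is 0.4 * dv_rel * tau per step; landing
# positions advance by the programmed step length relative to the trailing
# heel, so the walker drifts forward at a constant speed v_d satisfying
#   v_d * T = L - v * T + 0.4 * (v + v_d) * tau.
solve_drift <- function(p) {
  k <- 0.4 * p$contact_tau
  (p$step_length - p$comfortable_speed * p$step_time +
     p$comfortable_speed * k) / (p$step_time - k)
}

# Stance-entry velocity-blend shape: g(0)=1, g'(0)=0, g(1)=g'(1)=g''(1)=0.
entry_g <- function(u) {
  out <- numeric(length(u))
  i <- u > 0 & u < 1
  out[u <= 0] <- 1
  out[i] <- (1 - u[i])^3 * (1 + 3 * u[i])
  out
}
# Integral of entry_g from 0 to u; G(1) = 0.4.
entry_G <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u - 2 * u^3 + 2 * u^4 - 0.6 * u^5
}

#' Generate a synthetic treadmill-walking trial
#'
#' Builds a [gait_trial()] from a kinematic template together with its
#' ground truth. Heel strikes alternate at the programmed step time; during
#' stance each heel follows its belt backward (with a short smooth contact
#' blend), during swing it travels along a quintic that lands exactly at the
#' programmed position and time with the heel-to-pelvis AP excursion at a
#' locally symmetric maximum, so heel-strike detection on the filtered
#' signal recovers the programmed events. Perturbations are injected during
#' generation: platform sway displaces every ML coordinate and the platform
#' channel, belt perturbations rewrite the non-dominant belt channel and
#' carry the stance foot with it, sensory perturbations only log an event.
#' Scripted step deviations are applied to the six post-perturbation steps
#' and decay back to the baseline pattern afterwards through a relaxation of
#' lane, progression and timing offsets (factor 0.5 per step).
#'
#' @param params a [gait_params()].
#' @param perturbations list of perturbation requests; each element is a
#'   list with `ptype`, `at_stride` (index among non-dominant strides),
#'   optional `spec` ([perturbation_spec()]), optional `script`
#'   ([response_script()]; defaults to [default_script()]), optional
#'   `mos_targets` (list with `mos_ml` and/or `mos_ap` length-6 vectors of
#'   desired margin-of-stability deviations, converted to foot placements
#'   analytically, overriding `d_ml`/`d_ap`), and optional
#'   `repetition_index`.
#' @return a `gait_trial` with an extra element `truth`: list with
#'   `params`, `strikes` (programmed events: `k`, `time`, `sample`, `side`),
#'   `steps` (per-step true parameter values and deviations from baseline,
#'   with post-perturbation labels), and `baseline_values` (the analytic
#'   steady-state value of each gait parameter).
#' @export
make_gait_trial <- function(params = gait_params(), perturbations = list()) {
  p <- params
  fs <- p$fs
  T0 <- p$step_time
  v0 <- p$comfortable_speed
  dom <- p$dominant_side
  nd <- if (dom == "R") "L" else "R"
  n <- round(p$duration * fs)
  tg <- (seq_len(n) - 1) / fs
  omega0 <- sqrt(9.81 / (1.34 * p$troch_height))
  vd <- solve_drift(p)
  tau <- p$contact_tau

  # --- strike schedule ------------------------------------------------
  # strike k at ~k*T0; k odd -> L, k even -> R; virtual strikes k in
  # {-1, 0} seed the initial stance and k up to K_ext complete the last
  # swing segments.
  K_ext <- ceiling((p$duration + 2 * T0) / T0) + 1L
  ks <- -1L:K_ext
  nk <- length(ks)
  side_k <- ifelse(ks %% 2L == 0L, "R", "L")
  sign_k <- ifelse(side_k == "R", 1, -1)

  # resolve per-strike scripted deviations
  d_time <- d_ap <- d_ml <- numeric(nk)
  mos_ml_tgt <- mos_ap_tgt <- rep(NA_real_, nk)
  post_of <- rep(NA_integer_, nk)   # 1..6 within a window
  event_of <- rep(NA_integer_, nk)  # perturbation list index

  perturbations <- lapply(seq_along(perturbations), function(i) {
    pe <- perturbations[[i]]
    pe$ptype <- match.arg(pe$ptype, PERTURBATION_TYPES)
    if (is.null(pe$spec)) pe$spec <- perturbation_spec(pe$ptype)
    if (is.null(pe$script)) pe$script <- default_script(pe$ptype)
    if (is.null(pe$repetition_index)) pe$repetition_index <- i
    pe
  })

  nd_ks <- ks[side_k == nd & ks >= 1L]
  trig_k <- integer(length(perturbations))
  for (i in seq_along(perturbations)) {
    pe <- perturbations[[i]]
    if (pe$at_stride < 1L || pe$at_stride > length(nd_ks)) {
      gs_stop("validation", sprintf(
        "at_stride %d: no such non-dominant stride", pe$at_stride))
    }
    k <- nd_ks[pe$at_stride]
    trig_k[i] <- k
    rows <- match(k + 1:6, ks)
    if (anyNA(rows) || (k + 6L) * T0 > p$duration - 2 * T0) {
      gs_stop("validation",
              "perturbation too close to the end of the trial")
    }
    d_time[rows] <- pe$script$d_time
    d_ap[rows] <- pe$script$d_ap
    d_ml[rows] <- pe$script$d_ml
    if (!is.null(pe$mos_targets$mos_ml)) mos_ml_tgt[rows] <- pe$mos_targets$mos_ml
    if (!is.null(pe$mos_targets$mos_ap)) mos_ap_tgt[rows] <- pe$mos_targets$mos_ap
    post_of[rows] <- 1:6
    event_of[rows] <- i
  }

  # strike times: scripted deviations are applied exactly inside a
  # perturbation window; the accumulated timing offset decays by 0.5 per
  # step outside windows (relaxation back to the baseline rhythm)
  t_k <- numeric(nk)
  t_k[1L] <- -T0
  q <- 0
  for (j in 2:nk) {
    if (!is.na(post_of[j])) {
      dt <- T0 + d_time[j]
      q <- q + d_time[j]
    } else {
      dt <- T0 - 0.5 * q
      q <- 0.5 * q
    }
    t_k[j] <- t_k[j - 1L] + dt
  }

  # --- belt channels --------------------------------------------------
  belt <- list(L = rep(v0, n), R = rep(v0, n))
  for (i in seq_along(perturbations)) {
    pe <- perturbations[[i]]
    if (pe$ptype %in% c("belt_acc", "belt_dec")) {
      sp <- pe$spec
      hold <- if (is.na(sp$hold)) T0 else sp$hold
      fun <- belt_profile_fun(v0, sp$factor, sp$ramp, hold)
      t_trig <- t_k[match(trig_k[i], ks)]
      belt[[nd]] <- ifelse(tg >= t_trig & tg <= t_trig + 2 * sp$ramp + hold,
                           fun(tg - t_trig), belt[[nd]])
    }
  }
  belt_fun <- list(
    L = stats::approxfun(tg, belt$L, rule = 2),
    R = stats::approxfun(tg, belt$R, rule = 2)
  )
  # cumulative belt displacement per side (trapezoidal, exact for the
  # piecewise-constant baseline)
  cum_trapz <- function(x) c(0, cumsum((x[-1L] + x[-length(x)]) / 2)) / fs
  belt_int <- list(
    L = stats::approxfun(tg, cum_trapz(belt$L), rule = 2),
    R = stats::approxfun(tg, cum_trapz(belt$R), rule = 2)
  )

  # --- platform channel -----------------------------------------------
  plat_parts <- list()
  for (i in seq_along(perturbations)) {
    pe <- perturbations[[i]]
    if (pe$ptype %in% c("sway_ipsi", "sway_contra")) {
      sp <- pe$spec
      dir_nd <- if (nd == "L") -1 else 1
      direction <- if (pe$ptype == "sway_ipsi") dir_nd else -dir_nd
      t_trig <- t_k[match(trig_k[i], ks)]
      f <- sway_profile_funs(sp$displacement, sp$duration, sp$a_max, direction)
      plat_parts[[length(plat_parts) + 1L]] <-
        list(t0 = t_trig, pos = f$pos, vel = f$vel)
      if (isTRUE(sp$return_to_center)) {
        r <- minjerk_move_funs(-direction * sp$displacement, sp$return_duration)
        plat_parts[[length(plat_parts) + 1L]] <-
          list(t0 = t_trig + sp$return_delay, pos = r$pos, vel = r$vel)
      }
    }
  }
  plat_pos <- function(t) {
    out <- numeric(length(t))
    for (part in plat_parts) out <- out + part$pos(t - part$t0)
    out
  }
  plat_vel <- function(t) {
    out <- numeric(length(t))
    for (part in plat_parts) out <- out + part$vel(t - part$t0)
    out
  }
  platform_ml <- plat_pos(tg)
  if (length(plat_parts) && max(abs(platform_ml)) > 0.15 + 1e-9) {
    gs_stop("excursion_exceeded", sprintf(
      "platform excursion %.3f m exceeds the 0.15 m bound",
      max(abs(platform_ml))))
  }

  # --- CoM / pelvis model (analytic, platform added later) -------------
  W <- p$step_width
  L <- p$step_length
  A1 <- 0   # landing position of strike k = -1
  com_line <- function(t) A1 + vd * (t - t_k[1L])
  com_ap_f <- function(t) {
    com_line(t) - p$heel_lead - p$ap_osc_amp +
      p$ap_osc_amp * cos(2 * pi * t / T0)
  }
  com_ap_d <- function(t) vd - p$ap_osc_amp * (2 * pi / T0) * sin(2 * pi * t / T0)
  com_ml_f <- function(t) p$com_sway_amp * sin(pi * t / T0)
  com_ml_d <- function(t) p$com_sway_amp * (pi / T0) * cos(pi * t / T0)
  com_vt_f <- function(t) p$troch_height + p$vt_osc_amp * cos(2 * pi * t / T0)

  # analytic steady-state gait parameter values (baseline reference)
  base_vals <- c(
    step_time = T0,
    step_length = L,
    step_width = W,
    mos_ml = W / 2 - p$com_sway_amp * (pi / T0) / omega0,
    mos_ap = (vd + v0) / omega0 - p$heel_lead
  )

  # --- sequential landing recursion ------------------------------------
  A <- numeric(nk)      # AP landing positions
  m <- numeric(nk)      # ML landing positions
  dv_k <- numeric(nk)   # contact-blend velocity step
  o <- 0                # AP progression offset vs baseline line
  o_scr <- 0            # part of `o` created by the current window's script
  lane_e <- c(L = 0, R = 0)  # per-foot lane offsets
  true_len <- true_wid <- true_mml <- true_map <- rep(NA_real_, nk)

  pelvis_d <- com_ap_d  # pelvis tracks the CoM horizontally
  for (j in seq_len(nk)) {
    s <- side_k[j]
    dv_k[j] <- belt_fun[[s]](t_k[j]) + pelvis_d(t_k[j])
    if (j <= 2L) {  # virtual seed strikes: on the baseline landing line
      A[j] <- A1 + vd * (t_k[j] - t_k[1L])
      m[j] <- sign_k[j] * W / 2
      next
    }
    jp <- j - 1L
    sp_side <- side_k[jp]
    # trailing-heel position at this strike (stance since strike jp)
    u_tr <- (t_k[j] - t_k[jp]) / tau
    trail <- A[jp] -
      (belt_int[[sp_side]](t_k[j]) - belt_int[[sp_side]](t_k[jp])) +
      dv_k[jp] * tau * entry_G(u_tr)
    in_window <- !is.na(post_of[j])
    # AP landing. Scripted placements are exact; the part of the
    # progression offset NOT created by the script (e.g. the stance foot
    # having been carried by a belt perturbation) relaxes by 0.5 per step,
    # emulating recovery toward the baseline progression.
    if (!is.na(mos_ap_tgt[j])) {
      xcom_ap <- com_ap_f(t_k[j]) +
        (com_ap_d(t_k[j]) + belt_fun[[s]](t_k[j])) / omega0
      A[j] <- xcom_ap - (base_vals[["mos_ap"]] + mos_ap_tgt[j])
      o <- A[j] - (A1 + vd * (t_k[j] - t_k[1L]))
      o_scr <- o
    } else if (in_window) {
      A[j] <- trail + L + d_ap[j] - 0.5 * (o - o_scr)
      o <- A[j] - (A1 + vd * (t_k[j] - t_k[1L]))
      o_scr <- o_scr + d_ap[j]
    } else {
      A[j] <- trail + L - 0.5 * o
      o <- A[j] - (A1 + vd * (t_k[j] - t_k[1L]))
      o_scr <- 0
    }
    # ML landing: MoS target, exact scripted lane inside a window, or
    # per-foot relaxation toward the nominal lane
    if (!is.na(mos_ml_tgt[j])) {
      xcom_ml_free <- com_ml_f(t_k[j]) + com_ml_d(t_k[j]) / omega0
      m[j] <- sign_k[j] * (base_vals[["mos_ml"]] + mos_ml_tgt[j]) +
        xcom_ml_free + plat_vel(t_k[j]) / omega0
    } else if (in_window) {
      m[j] <- m[jp] + sign_k[j] * (W + d_ml[j])
    } else {
      m[j] <- sign_k[j] * W / 2 + 0.5 * lane_e[[s]]
    }
    lane_e[[s]] <- m[j] - sign_k[j] * W / 2
    # true measured values at this strike
    true_len[j] <- A[j] - trail
    true_wid[j] <- abs(m[j] - m[jp])
    true_mml[j] <- sign_k[j] *
      (m[j] - com_ml_f(t_k[j]) - com_ml_d(t_k[j]) / omega0 -
         plat_vel(t_k[j]) / omega0)
    true_map[j] <- com_ap_f(t_k[j]) +
      (com_ap_d(t_k[j]) + belt_fun[[s]](t_k[j])) / omega0 - A[j]
  }

  # --- foot trajectories ------------------------------------------------
  heel <- list(L = matrix(0, n, 3, dimnames = list(NULL, TRIAL_AXES)),
               R = matrix(0, n, 3, dimnames = list(NULL, TRIAL_AXES)))
  for (s in c("L", "R")) {
    own <- which(side_k == s)
    for (ii in seq_along(own)) {
      j <- own[ii]
      t_b <- t_k[j]
      t_next <- if (ii < length(own)) t_k[own[ii + 1L]] else Inf
      j_next <- if (ii < length(own)) own[ii + 1L] else NA_integer_
      t_sw <- t_b + p$stance_fraction * (t_next - t_b)
      # stance: belt tracking with contact blend
      i_st <- which(tg >= t_b & tg < min(t_sw, p$duration))
      if (length(i_st)) {
        tt <- tg[i_st]
        heel[[s]][i_st, "y"] <- A[j] -
          (belt_int[[s]](tt) - belt_int[[s]](t_b)) +
          dv_k[j] * tau * entry_G((tt - t_b) / tau)
        heel[[s]][i_st, "x"] <- m[j]
        heel[[s]][i_st, "z"] <- 0.02
      }
      if (ii == 1L && t_b > tg[1L]) {  # before the first strike: hold
        i_pre <- which(tg < t_b)
        heel[[s]][i_pre, "y"] <- A[j] + belt_int[[s]](t_b) -
          belt_int[[s]](tg[i_pre])
        heel[[s]][i_pre, "x"] <- m[j]
        heel[[s]][i_pre, "z"] <- 0.02
      }
      # swing toward the next own strike
      if (is.finite(t_next) && t_sw < p$duration) {
        i_sw <- which(tg >= t_sw & tg < min(t_next, p$duration))
        if (length(i_sw)) {
          tt <- tg[i_sw]
          u_sw <- (t_sw - t_b) / tau
          p_sw <- A[j] - (belt_int[[s]](t_sw) - belt_int[[s]](t_b)) +
            dv_k[j] * tau * entry_G(u_sw)
          v_sw <- -belt_fun[[s]](t_sw) + dv_k[j] * entry_g(u_sw)
          # end the swing with a downward acceleration matching the mean
          # curvature of the stance-entry blend, so the heel-to-pelvis
          # excursion peaks symmetrically at the strike and zero-phase
          # filtering does not shift the detected event
          a_land <- -1.6875 * dv_k[j_next] / tau
          heel[[s]][i_sw, "y"] <- quintic_segment(
            tt, t_sw, t_next, p_sw, A[j_next],
            v0 = v_sw, v1 = pelvis_d(t_next),
            a0 = 0, a1 = a_land
          )
          su <- (tt - t_sw) / (t_next - t_sw)
          heel[[s]][i_sw, "x"] <- m[j] + (m[j_next] - m[j]) * minjerk_s(su)
          heel[[s]][i_sw, "z"] <- 0.02 + p$swing_lift * sin(pi * su)^2
        }
      }
    }
  }

  # --- assemble channels ------------------------------------------------
  com <- cbind(x = com_ml_f(tg), y = com_ap_f(tg), z = com_vt_f(tg))
  pelvis <- cbind(x = com[, "x"], y = com[, "y"], z = 0.95)
  trunk <- cbind(
    x = com[, "x"] + 0.004 * sin(pi * tg / T0 + 0.9),
    y = com[, "y"] + 0.010 * sin(2 * pi * tg / T0 + 0.4) +
      0.004 * sin(3 * pi * tg / T0 + 1.7),
    z = 1.35 + 0.012 * cos(2 * pi * tg / T0 + 0.2)
  )
  troch_L <- cbind(x = com[, "x"] - 0.10, y = com[, "y"] - 0.02,
                   z = p$troch_height)
  troch_R <- cbind(x = com[, "x"] + 0.10, y = com[, "y"] - 0.02,
                   z = p$troch_height)
  mall <- lapply(heel, function(h) {
    cbind(x = h[, "x"], y = h[, "y"] + 0.04, z = h[, "z"] + 0.05)
  })
  markers <- list(
    heel_L = heel$L, heel_R = heel$R,
    malleolus_L = mall$L, malleolus_R = mall$R,
    trochanter_L = troch_L, trochanter_R = troch_R,
    pelvis = pelvis, trunk = trunk
  )
  # platform displaces everything medio-laterally
  for (nm in names(markers)) markers[[nm]][, "x"] <- markers[[nm]][, "x"] + platform_ml
  com[, "x"] <- com[, "x"] + platform_ml

  # noise (the only stochastic part; RNG state restored afterwards)
  if (p$marker_noise_sd > 0 || p$trunk_noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(p$seed)
    for (nm in names(markers)) {
      if (p$marker_noise_sd > 0) {
        markers[[nm]] <- markers[[nm]] +
          matrix(stats::rnorm(3L * n, sd = p$marker_noise_sd), n, 3L)
      }
    }
    if (p$trunk_noise_sd > 0) {
      markers$trunk <- markers$trunk +
        matrix(stats::rnorm(3L * n, sd = p$trunk_noise_sd), n, 3L)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }

  # --- events + truth ---------------------------------------------------
  events <- empty_events()
  for (i in seq_along(perturbations)) {
    pe <- perturbations[[i]]
    tt <- t_k[match(trig_k[i], ks)]
    events <- rbind(events, data.frame(
      ptype = pe$ptype,
      trigger_time = tt,
      trigger_sample = as.integer(round(tt * fs)) + 1L,
      repetition_index = as.integer(pe$repetition_index),
      params_json = as.character(jsonlite::toJSON(
        pe$spec[setdiff(names(pe$spec), "ptype")], auto_unbox = TRUE)),
      stringsAsFactors = FALSE
    ))
  }

  real <- which(ks >= 1L & t_k <= p$duration - 2 * T0 - 0.01)
  strikes <- data.frame(
    k = ks[real],
    time = t_k[real],
    sample = as.integer(round(t_k[real] * fs)) + 1L,
    side = side_k[real],
    stringsAsFactors = FALSE
  )
  step_rows <- real[-1L]
  steps <- data.frame(
    end_k = ks[step_rows],
    hs_time = t_k[step_rows],
    hs_sample = as.integer(round(t_k[step_rows] * fs)) + 1L,
    side = side_k[step_rows],
    step_time = diff(t_k)[step_rows - 1L],
    step_length = true_len[step_rows],
    step_width = true_wid[step_rows],
    mos_ml = true_mml[step_rows],
    mos_ap = true_map[step_rows],
    event = event_of[step_rows],
    post_index = post_of[step_rows],
    stringsAsFactors = FALSE
  )
  for (par in GAIT_PARAMETERS) {
    steps[[paste0("dev_", par)]] <- steps[[par]] - base_vals[[par]]
  }

  trial <- gait_trial(
    fs = fs, markers = markers, com = com,
    belt_speed_L = belt$L, belt_speed_R = belt$R,
    platform_ml = platform_ml,
    meta = list(dominant_side = dom, comfortable_speed = v0,
                group = "synthetic"),
    events = events
  )
  trial$truth <- list(params = p, strikes = strikes, steps = steps,
                      baseline_values = base_vals, drift_speed = vd,
                      perturbations = perturbations)
  trial
}

#' Inject one perturbation into a synthetic trial
#'
#' Regenerates the trial from its stored parameters with one more
#' perturbation event; generation is deterministic given the seed, so the
#' unperturbed samples are unchanged.
#'
#' @param trial a trial produced by [make_gait_trial()].
#' @param ptype perturbation type.
#' @param at_stride index among non-dominant strides at which to trigger.
#' @param spec optional [perturbation_spec()].
#' @param script optional [response_script()]; defaults to the type's
#'   [default_script()].
#' @param mos_targets optional MoS-deviation targets (see
#'   [make_gait_trial()]).
#' @return a new `gait_trial` with the added event and updated truth.
#' @export
inject_perturbation <- function(trial, ptype, at_stride, spec = NULL,
                                script = NULL, mos_targets = NULL) {
  if (is.null(trial$truth)) {
    gs_stop("validation", "inject_perturbation needs a synthetic trial with truth")
  }
  reqs <- c(trial$truth$perturbations,
            list(list(ptype = ptype, at_stride = at_stride, spec = spec,
                      script = script, mos_targets = mos_targets)))
  make_gait_trial(trial$truth$params, reqs)
}

#' Generate a full synthetic perturbation session
#'
#' One baseline trial long enough for the 100-stride baseline analyses plus
#' six perturbation trials (one per type, four repetitions each, triggered
#' at non-dominant heel strikes with at least 15 washout strides between
#' repetitions), presented in seeded pseudo-random order.
#'
#' @param params a [gait_params()]; `duration` is overridden per trial.
#' @param seed integer seed driving the trial order, trigger jitter and any
#'   noise.
#' @param baseline_duration seconds of baseline walking (default gives
#'   > 110 strides at the default step time).
#' @param washout_strides minimum strides between repetitions.
#' @return list with `baseline` (a `gait_trial`), `trials` (named list of
#'   six perturbation trials) and `order` (presentation order).
#' @export
make_session <- function(params = gait_params(), seed = params$seed,
                         baseline_duration = 130, washout_strides = 15) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  order <- sample(PERTURBATION_TYPES)
  bl_params <- params
  bl_params$duration <- baseline_duration
  bl_params$seed <- seed
  baseline <- make_gait_trial(bl_params)
  first <- 10L + sample.int(3L, 6L, replace = TRUE)
  jitter <- matrix(sample.int(3L, 24L, replace = TRUE) - 1L, 6L, 4L)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  trials <- list()
  for (i in seq_along(order)) {
    ptype <- order[i]
    strides <- cumsum(c(first[i], washout_strides + jitter[i, 2:4]))
    tp <- params
    tp$duration <- (max(strides) + 10) * 2 * params$step_time
    tp$seed <- seed + i
    perts <- lapply(seq_along(strides), function(r) {
      list(ptype = ptype, at_stride = strides[r], repetition_index = r)
    })
    trials[[ptype]] <- make_gait_trial(tp, perts)
  }
  list(baseline = baseline, trials = trials[order], order = order)
}

#' Analyse a synthetic session end to end
#'
#' Runs the full pipeline on a [make_session()] result: heel-strike
#' detection and step measurement on the baseline trial, the 100-step
#' baseline summary, peri-perturbation windows and 6S per repetition for
#' every perturbation trial, averaging over the last three repetitions.
#'
#' @param session a [make_session()] result.
#' @param filter logical, passed to the measurement functions.
#' @param n_per_side baseline steps per side.
#' @return list with `baseline_steps`, `baseline`, `six_s_reps`,
#'   `six_s` (averaged), `peri` (per-label step table) and `windows`.
#' @export
analyze_session <- function(session, filter = TRUE, n_per_side = 100) {
  bl <- session$baseline
  params <- xcom_params(trial = bl)
  ev <- detect_heel_strikes(bl)
  bl_steps <- step_table(bl, ev, params = params, filter = filter)
  baseline <- baseline_summary(bl_steps, n_per_side = n_per_side)
  all_six <- list()
  all_windows <- list()
  for (nm in names(session$trials)) {
    res <- perturbation_responses(session$trials[[nm]], baseline,
                                  params = params, filter = filter)
    all_six[[nm]] <- res$six_s
    all_windows <- c(all_windows, res$windows)
  }
  six_reps <- as.data.frame(data.table::rbindlist(all_six))
  list(
    baseline_steps = bl_steps,
    baseline = baseline,
    six_s_reps = six_reps,
    six_s = average_repetitions(six_reps),
    peri = peri_step_table(all_windows),
    windows = all_windows
  )
}
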