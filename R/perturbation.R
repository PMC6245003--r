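#' Extract the peri-perturbation step window
#'
#' Perturbations are triggered at a non-dominant heel strike. The window
#' comprises the six steps immediately preceding the trigger (the step
#' terminated by the triggering strike is the last pre step) and the six
#' steps after it, labelled 1D, 2ND, 3D, 4ND, 5D, 6ND: post step k is the
#' step terminated by the k-th heel strike after the trigger, and step 1D
#' must land on the dominant side.
#'
#' @param steps step table from [step_table()].
#' @param event one row of a trial's event log (list or single-row
#'   data.frame with `trigger_sample`, `ptype`, `repetition_index`).
#' @param dominant_side "L" or "R".
#' @param tol_samples tolerance for matching the trigger to a heel-strike
#'   sample (default 3).
#' @param other_events optional data.frame of the trial's remaining events;
#'   when given, an error is raised if another trigger falls inside this
#'   window.
#' @return object of class `peri_window`: list with `event`, `pre` (6 rows,
#'   labels "PD"/"NPD" by side) and `post` (6 rows, labels "1D".."6ND").
#' @export
extract_peri_window <- function(steps, event, dominant_side,
                                tol_samples = 3, other_events = NULL) {
  event <- as.list(event)
  trig <- event$trigger_sample
  d <- abs(steps$hs_sample - trig)
  k <- which.min(d)
  if (!length(k) || d[k] > tol_samples) {
    gs_stop("trigger_misaligned", sprintf(
      "trigger sample %d is not at a heel strike (nearest is %d samples away)",
      trig, if (length(k)) d[k] else NA_integer_))
  }
  if (steps$side[k] == dominant_side) {
    gs_stop("trigger_misaligned",
            "trigger heel strike is on the dominant side; expected non-dominant")
  }
  if (k < 6L || k + 6L > nrow(steps)) {
    gs_stop("incomplete_window",
            "need 6 steps before and after the trigger within the trial")
  }
  pre <- steps[(k - 5L):k, , drop = FALSE]
  post <- steps[(k + 1L):(k + 6L), , drop = FALSE]
  if (post$side[1L] != dominant_side) {
    gs_stop("trigger_misaligned",
            "first post-perturbation step does not land on the dominant side")
  }
  pre$label <- ifelse(pre$side == dominant_side, "PD", "NPD")
  post$label <- paste0(1:6, rep(c("D", "ND"), 3L))
  if (!is.null(other_events) && nrow(other_events)) {
    span <- range(c(pre$hs_sample, post$hs_sample)) +
      c(-1, 1) * tol_samples
    inside <- other_events$trigger_sample >= span[1L] &
      other_events$trigger_sample <= span[2L]
    if (any(inside)) {
      gs_stop("window_overlap", sprintf(
        "another perturbation (repetition %s) falls inside this window",
        paste(other_events$repetition_index[inside], collapse = ", ")))
    }
  }
  structure(list(event = event, pre = pre, post = post),
            class = "peri_window")
}

#' @export
print.peri_window <- function(x, ...) {
  cat(sprintf("<peri_window> %s (repetition %s): post steps %s\n",
              x$event$ptype, x$event$repetition_index,
              paste(x$post$label, collapse = " ")))
  invisible(x)
}

#' 6S: total deviation from baseline over six post-perturbation steps
#'
#' For one gait parameter, 6S sums the absolute deviations of the six
#' post-perturbation steps from the baseline mean of the matching side:
#' `6S = sum_{i=1..2} sum_{j=1..3} |B(i) - P(i + (j-1)*2)|`, with i = 1 the
#' dominant side (post steps 1D, 3D, 5D compared with the BD mean) and
#' i = 2 the non-dominant side (2ND, 4ND, 6ND vs the BND mean). It is the
#' L1 norm of the side-matched deviation vector, so it captures overall
#' departure from steady-state walking regardless of how recovery is
#' distributed over the six steps.
#'
#' @param baseline a [baseline_summary()].
#' @param window a [extract_peri_window()] result.
#' @param parameter one of `step_time`, `step_length`, `step_width`,
#'   `mos_ml`, `mos_ap`.
#' @return single non-negative number, in the units of `parameter`.
#' @export
six_s <- function(baseline, window, parameter) {
  stopifnot(parameter %in% baseline$parameter)
  post <- window$post
  if (nrow(post) != 6L || anyNA(post[[parameter]])) {
    gs_stop("incomplete_window", "six finite post-perturbation steps required")
  }
  b_d <- baseline_mean(baseline, parameter, "D")
  b_nd <- baseline_mean(baseline, parameter, "ND")
  b <- ifelse(post$dominant, b_d, b_nd)
  sum(abs(b - post[[parameter]]))
}

#' 6S for every gait parameter of one window
#'
#' @inheritParams six_s
#' @param parameters parameters to evaluate.
#' @return data.frame with columns `ptype`, `repetition_index`, `parameter`,
#'   `six_s`.
#' @export
six_s_all <- function(baseline, window, parameters = GAIT_PARAMETERS) {
  data.frame(
    ptype = window$event$ptype,
    repetition_index = window$event$repetition_index,
    parameter = parameters,
    six_s = vapply(parameters, function(p) six_s(baseline, window, p),
                   numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Average 6S over the last repetitions of each perturbation trial
#'
#' Perturbation measures are averaged over the last `keep_last` repetitions
#' of each perturbation type (default 3 of the 4 presented), discarding the
#' first exposure, whose startle component is not representative.
#'
#' @param results data.frame of per-repetition values as produced by
#'   [six_s_all()] (columns `ptype`, `repetition_index`, `parameter`,
#'   `six_s`), possibly concatenated over trials.
#' @param keep_last number of final repetitions to keep per type.
#' @return data.frame with columns `ptype`, `parameter`, `six_s` (mean over
#'   kept repetitions) and `n_reps` (how many were used). When fewer than
#'   `keep_last` repetitions exist, all are used and a warning is issued.
#' @export
average_repetitions <- function(results, keep_last = 3) {
  dt <- data.table::as.data.table(results)
  out <- dt[order(repetition_index),
            {
              n <- .N
              if (n < keep_last) {
                gs_warn("few_repetitions", sprintf(
                  "%s/%s: only %d repetition(s) available; averaging all",
                  ptype[1L], parameter[1L], n))
              }
              kept <- utils::tail(six_s, keep_last)
              list(six_s = mean(kept), n_reps = length(kept))
            },
            by = .(ptype, parameter)]
  as.data.frame(out)
}

#' Per-label step summary across windows
#'
#' Summarizes each gait parameter by peri-perturbation label: PD and NPD are
#' the per-window means of the three same-side pre steps; 1D through 6ND are
#' the individual post steps. Means and SDs are taken across windows,
#' yielding the step-series table that underlies recovery-course plots and
#' external statistics.
#'
#' @param windows list of [extract_peri_window()] results.
#' @param parameters gait parameters to include.
#' @return data.frame with columns `ptype`, `label` (ordered factor
#'   PD, NPD, 1D, ..., 6ND), `parameter`, `mean`, `sd`, `n_windows`.
#' @export
peri_step_table <- function(windows, parameters = GAIT_PARAMETERS) {
  stopifnot(length(windows) >= 1L)
  labels <- c("PD", "NPD", paste0(1:6, rep(c("D", "ND"), 3L)))
  rows <- lapply(windows, function(w) {
    pre <- w$pre
    post <- w$post
    do.call(rbind, lapply(parameters, function(p) {
      data.frame(
        ptype = w$event$ptype,
        label = c("PD", "NPD", post$label),
        parameter = p,
        value = c(mean(pre[[p]][pre$label == "PD"]),
                  mean(pre[[p]][pre$label == "NPD"]),
                  post[[p]]),
        stringsAsFactors = FALSE
      )
    }))
  })
  dt <- data.table::rbindlist(rows)
  out <- dt[, .(mean = mean(value),
                sd = if (.N > 1L) stats::sd(value) else 0,
                n_windows = .N),
            by = .(ptype, label, parameter)]
  out <- as.data.frame(out)
  out$label <- factor(out$label, levels = labels, ordered = TRUE)
  out[order(out$ptype, out$parameter, out$label), ]
}

#' Analyse every perturbation in a trial
#'
#' Convenience wrapper: detects heel strikes, builds the step table,
#' extracts one peri-window per logged event (checking for window overlap)
#' and evaluates 6S per repetition.
#'
#' @param trial a [gait_trial()] whose event log is non-empty.
#' @param baseline a [baseline_summary()] computed on the matching baseline
#'   trial.
#' @param params optional [xcom_params()] shared with the baseline
#'   computation.
#' @param filter logical, passed to the measurement functions.
#' @return list with `windows` (list of `peri_window`), `six_s`
#'   (per-repetition data.frame) and `steps` (the full step table).
#' @export
perturbation_responses <- function(trial, baseline, params = NULL,
                                   filter = TRUE) {
  if (!nrow(trial$events)) gs_stop("validation", "trial has no events")
  events <- detect_heel_strikes(trial)
  steps <- step_table(trial, events, params = params, filter = filter)
  windows <- lapply(seq_len(nrow(trial$events)), function(i) {
    extract_peri_window(
      steps, trial$events[i, ], trial$meta$dominant_side,
      other_events = trial$events[-i, , drop = FALSE]
    )
  })
  six <- data.table::rbindlist(lapply(windows, six_s_all, baseline = baseline))
  list(windows = windows, six_s = as.data.frame(six), steps = steps)
}

#' Write tidy result tables
#'
#' Exports 6S results and the peri-step table as tab-separated files ready
#' for external statistics software.
#'
#' @param six_s data.frame from [average_repetitions()] (or per-repetition).
#' @param peri data.frame from [peri_step_table()], or `NULL`.
#' @param dir output directory (created if needed).
#' @param subject_id subject identifier column value.
#' @return invisibly, the paths written.
#' @export
write_results <- function(six_s, peri = NULL, dir = ".", subject_id = "S01") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  p1 <- file.path(dir, "six_s.tsv")
  data.table::fwrite(cbind(subject = subject_id, six_s), p1, sep = "\t")
  paths <- p1
  if (!is.null(peri)) {
    p2 <- file.path(dir, "peri_steps.tsv")
    data.table::fwrite(cbind(subject = subject_id, peri), p2, sep = "\t")
    paths <- c(paths, p2)
  }
  invisible(paths)
}
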