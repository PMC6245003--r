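#' Marker set required in every trial
#'
#' Lab-frame axis convention used throughout the package: X = medio-lateral
#' (positive toward the participant's right), Y = anterior-posterior
#' (positive in the progression direction), Z = vertical (up). Units are
#' meters, belt speeds m/s (positive = belt surface moving backward under
#' the foot), sampling in Hz. This convention is internal to the package.
#'
#' @format Character vector of the eight required marker names.
#' @export
TRIAL_MARKERS <- c(
  "heel_L", "heel_R", "malleolus_L", "malleolus_R",
  "trochanter_L", "trochanter_R", "pelvis", "trunk"
)

TRIAL_AXES <- c("x", "y", "z")

PERTURBATION_TYPES <- c(
  "sway_ipsi", "sway_contra", "belt_acc", "belt_dec", "visual", "auditory"
)

GAIT_PARAMETERS <- c("step_time", "step_length", "step_width", "mos_ml", "mos_ap")

#' Construct a gait trial
#'
#' A `gait_trial` bundles synchronized kinematic channels from one treadmill
#' recording: eight marker trajectories, the whole-body centre of mass (CoM),
#' the two belt-speed channels, the medio-lateral platform displacement, the
#' perturbation event log and subject metadata.
#'
#' @param fs sampling rate in Hz.
#' @param markers named list of n-by-3 numeric matrices (columns x, y, z; see
#'   [TRIAL_MARKERS] for the required names and the axis convention).
#' @param com n-by-3 matrix of whole-body CoM position (m). The CoM is an
#'   input channel here (computed upstream by a full-body model); if `NULL`,
#'   the midpoint of the two trochanter markers is used as a proxy and a
#'   warning is issued.
#' @param belt_speed_L,belt_speed_R belt-speed series (m/s).
#' @param platform_ml platform medio-lateral displacement series (m).
#' @param meta list with at least `dominant_side` ("L" or "R") and
#'   `comfortable_speed` (m/s); optionally `subject_id` and `group`.
#' @param events data.frame of perturbation events with columns `ptype`,
#'   `trigger_time` (s), `trigger_sample` (1-based index, authoritative),
#'   `repetition_index` (1-4) and `params_json`; may have zero rows.
#' @param extra optional data.frame of additional channels carried through
#'   file round trips but ignored by the analysis.
#' @return object of class `gait_trial` with elements `fs`, `t`, `markers`,
#'   `com`, `belt_speed_L`, `belt_speed_R`, `platform_ml`, `meta`, `events`,
#'   `extra`.
#' @seealso [read_trial()], [write_trial()], [validate_trial()]
#' @export
gait_trial <- function(fs, markers, com = NULL, belt_speed_L, belt_speed_R,
                       platform_ml = NULL, meta = list(), events = NULL,
                       extra = NULL) {
  n <- nrow(markers[[1L]])
  if (is.null(com)) {
    gs_warn("com_proxy",
            "no CoM channel supplied; using mid-trochanter proxy")
    com <- (markers[["trochanter_L"]] + markers[["trochanter_R"]]) / 2
  }
  if (is.null(platform_ml)) platform_ml <- numeric(n)
  if (is.null(events)) events <- empty_events()
  meta <- utils::modifyList(
    list(dominant_side = "R", comfortable_speed = NA_real_,
         subject_id = "S01", group = "synthetic"),
    meta
  )
  trial <- structure(
    list(
      fs = fs,
      t = seq(0, by = 1 / fs, length.out = n),
      markers = markers,
      com = com,
      belt_speed_L = belt_speed_L,
      belt_speed_R = belt_speed_R,
      platform_ml = platform_ml,
      meta = meta,
      events = events,
      extra = extra
    ),
    class = "gait_trial"
  )
  trial
}

empty_events <- function() {
  data.frame(
    ptype = character(), trigger_time = numeric(),
    trigger_sample = integer(), repetition_index = integer(),
    params_json = character(), stringsAsFactors = FALSE
  )
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf(
    "<gait_trial> %d samples @ %g Hz (%.1f s), dominant side %s, %d event(s)\n",
    length(x$t), x$fs, length(x$t) / x$fs, x$meta$dominant_side, nrow(x$events)
  ))
  invisible(x)
}

#' Validate a gait trial
#'
#' Checks the structural invariants of a [gait_trial()]: channel presence and
#' equal lengths, uniform time base, positive sampling rate and comfortable
#' speed, event samples within the trial and repetition indices in 1-4.
#' This is a reporting operation: it never throws.
#'
#' @param trial a `gait_trial`.
#' @return character vector of human-readable violations; empty iff valid.
#' @export
validate_trial <- function(trial) {
  problems <- character()
  if (!is.numeric(trial$fs) || length(trial$fs) != 1L || !is.finite(trial$fs) ||
      trial$fs <= 0) {
    problems <- c(problems, "fs must be a positive finite scalar")
  }
  missing <- setdiff(TRIAL_MARKERS, names(trial$markers))
  if (length(missing)) {
    problems <- c(problems, paste("missing marker channel(s):",
                                  paste(missing, collapse = ", ")))
  }
  n <- length(trial$t)
  for (m in intersect(TRIAL_MARKERS, names(trial$markers))) {
    mm <- trial$markers[[m]]
    if (!is.matrix(mm) || ncol(mm) != 3L || nrow(mm) != n) {
      problems <- c(problems, sprintf("marker %s is not an n-by-3 matrix", m))
    }
  }
  for (ch in c("com")) {
    if (!is.matrix(trial[[ch]]) || ncol(trial[[ch]]) != 3L ||
        nrow(trial[[ch]]) != n) {
      problems <- c(problems, sprintf("channel %s is not an n-by-3 matrix", ch))
    }
  }
  for (ch in c("belt_speed_L", "belt_speed_R", "platform_ml")) {
    if (length(trial[[ch]]) != n) {
      problems <- c(problems, sprintf("channel %s length differs from t", ch))
    }
  }
  if (n >= 2L && is.numeric(trial$fs) && trial$fs > 0) {
    dt <- diff(trial$t)
    if (any(dt <= 0) || max(abs(dt - 1 / trial$fs)) > 1e-6 / trial$fs) {
      problems <- c(problems,
                    "t is not strictly increasing with uniform step 1/fs")
    }
  }
  if (!is.null(trial$meta$comfortable_speed) &&
      !is.na(trial$meta$comfortable_speed) &&
      trial$meta$comfortable_speed <= 0) {
    problems <- c(problems, "comfortable_speed must be > 0")
  }
  if (!trial$meta$dominant_side %in% c("L", "R")) {
    problems <- c(problems, "dominant_side must be 'L' or 'R'")
  }
  ev <- trial$events
  if (nrow(ev)) {
    bad <- which(ev$trigger_sample < 1L | ev$trigger_sample > n)
    if (length(bad)) {
      problems <- c(problems, sprintf(
        "event(s) %s: trigger_sample outside trial",
        paste(bad, collapse = ", ")))
    }
    if (any(!ev$repetition_index %in% 1:4)) {
      problems <- c(problems, "event repetition_index must be in 1..4")
    }
    if (any(!ev$ptype %in% PERTURBATION_TYPES)) {
      problems <- c(problems, "unknown perturbation type in events")
    }
  }
  problems
}

assert_valid_trial <- function(trial) {
  problems <- validate_trial(trial)
  if (length(problems)) {
    gs_stop("validation",
            paste0("invalid trial:\n  ", paste(problems, collapse = "\n  ")))
  }
  invisible(trial)
}

trial_channel_names <- function() {
  c("t",
    as.vector(t(outer(TRIAL_MARKERS, TRIAL_AXES, paste, sep = "_"))),
    paste("com", TRIAL_AXES, sep = "_"),
    "belt_speed_L", "belt_speed_R", "platform_ml")
}

#' Write a trial to tab-separated files
#'
#' Writes one row per sample with columns `t`, `<marker>_x/_y/_z` for the
#' eight required markers, `com_x/_y/_z`, `belt_speed_L`, `belt_speed_R` and
#' `platform_ml`, plus any extra channels. Perturbation events go to a
#' sidecar `<stem>.events.tsv` with columns `ptype`, `trigger_time`,
#' `trigger_sample` (0-based in the file), `repetition_index`, `params_json`;
#' the sidecar is only written when the event log is non-empty.
#'
#' @param trial a valid `gait_trial`.
#' @param path output path for the sample table (e.g. `"trial.tsv"`).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  assert_valid_trial(trial)
  cols <- c(
    list(t = trial$t),
    stats::setNames(
      unlist(lapply(TRIAL_MARKERS, function(m) {
        lapply(seq_len(3L), function(j) trial$markers[[m]][, j])
      }), recursive = FALSE),
      as.vector(t(outer(TRIAL_MARKERS, TRIAL_AXES, paste, sep = "_")))
    ),
    stats::setNames(lapply(1:3, function(j) trial$com[, j]),
                    paste("com", TRIAL_AXES, sep = "_")),
    list(belt_speed_L = trial$belt_speed_L,
         belt_speed_R = trial$belt_speed_R,
         platform_ml = trial$platform_ml)
  )
  dt <- data.table::as.data.table(cols)
  if (!is.null(trial$extra) && ncol(trial$extra)) {
    dt <- cbind(dt, data.table::as.data.table(trial$extra))
  }
  hdr <- sprintf("# gaitstab trial: fs=%s dominant_side=%s comfortable_speed=%s subject_id=%s group=%s",
                 format(trial$fs, digits = 15),
                 trial$meta$dominant_side,
                 format(trial$meta$comfortable_speed, digits = 15),
                 trial$meta$subject_id, trial$meta$group)
  writeLines(hdr, path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  if (nrow(trial$events)) {
    ev <- trial$events
    ev$trigger_sample <- ev$trigger_sample - 1L  # 0-based on disk
    data.table::fwrite(ev, events_path(path), sep = "\t")
  } else if (file.exists(events_path(path))) {
    unlink(events_path(path))
  }
  invisible(path)
}

events_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0(".events.tsv")
}

#' Read a trial from tab-separated files
#'
#' Counterpart of [write_trial()]. Requires every channel listed in
#' [TRIAL_MARKERS] (with `_x`, `_y`, `_z` suffixes) plus `com_*`,
#' `belt_speed_L`, `belt_speed_R` and `platform_ml`; unknown columns are
#' preserved in `$extra` but ignored by the analysis. The event sidecar
#' `<stem>.events.tsv` is read when present; its `trigger_sample` column is
#' 0-based on disk (authoritative) and converted to 1-based indices.
#'
#' @param path path to a trial written by [write_trial()].
#' @param dialect file dialect; only `"tsv"` is supported. `"c3d"` is
#'   reserved for motion-capture C3D import and is not available in this
#'   build.
#' @return a validated [gait_trial()].
#' @export
read_trial <- function(path, dialect = c("tsv", "c3d")) {
  dialect <- match.arg(dialect)
  if (dialect == "c3d") {
    gs_stop("unsupported_dialect",
            "C3D import is not available; convert to the TSV dialect")
  }
  if (!file.exists(path)) gs_stop("io", paste("file not found:", path))
  first <- readLines(path, n = 1L)
  meta <- list()
  skip <- 0L
  if (startsWith(first, "# gaitstab trial:")) {
    skip <- 1L
    kv <- regmatches(first, gregexpr("[a-z_]+=[^ ]+", first))[[1L]]
    for (pair in kv) {
      key <- sub("=.*", "", pair)
      val <- sub("^[a-z_]+=", "", pair)
      meta[[key]] <- if (key %in% c("fs", "comfortable_speed"))
        as.numeric(val) else val
    }
  }
  dt <- data.table::fread(path, sep = "\t", skip = skip, header = TRUE,
                          data.table = FALSE)
  required <- trial_channel_names()
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    gs_stop("missing_channel",
            paste("missing required channel(s):", paste(missing, collapse = ", ")))
  }
  tvec <- dt$t
  if (length(tvec) >= 2L) {
    dtv <- diff(tvec)
    if (any(dtv <= 0) || (max(dtv) - min(dtv)) > 1e-6 * stats::median(dtv)) {
      gs_stop("bad_time_base", "time vector is not uniformly increasing")
    }
  }
  fs <- meta$fs
  if (is.null(fs)) fs <- 1 / stats::median(diff(tvec))
  markers <- stats::setNames(lapply(TRIAL_MARKERS, function(m) {
    mm <- as.matrix(dt[, paste(m, TRIAL_AXES, sep = "_")])
    colnames(mm) <- TRIAL_AXES
    mm
  }), TRIAL_MARKERS)
  com <- as.matrix(dt[, paste("com", TRIAL_AXES, sep = "_")])
  colnames(com) <- TRIAL_AXES
  extra_cols <- setdiff(names(dt), required)
  extra <- if (length(extra_cols)) dt[, extra_cols, drop = FALSE] else NULL

  events <- empty_events()
  ep <- events_path(path)
  if (file.exists(ep)) {
    events <- data.table::fread(ep, sep = "\t", data.table = FALSE,
                                colClasses = list(character = "params_json"))
    events$trigger_sample <- as.integer(events$trigger_sample) + 1L  # to 1-based
  }
  trial <- gait_trial(
    fs = fs, markers = markers, com = com,
    belt_speed_L = dt$belt_speed_L, belt_speed_R = dt$belt_speed_R,
    platform_ml = dt$platform_ml,
    meta = meta[setdiff(names(meta), "fs")],
    events = events, extra = extra
  )
  assert_valid_trial(trial)
  trial
}
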