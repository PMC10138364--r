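#' @name temporal
#' @title Timed pose verification and minute-level monitoring
#' @description
#' The timed assessment protocol: one skeleton assessment every 5 s, a
#' 3-assessment verification window spanning 15 s, a motion score between
#' adjacent assessments to split walking from standing, a 1-minute
#' extension fused with wristband sleep-state and heart rate to split
#' lying-in-bed from sleeping, per-minute reassessment, and a per-day
#' activity ledger of hours spent in each pose.
NULL

#' Sample periodic assessments from a frame stream
#'
#' Keeps one assessment per sampling period per subject: at 10 FPS over a
#' 60 s stream with the default 5 s period this inspects 600 frames and
#' retains 12 assessments. For each tick the frame nearest in time that
#' contains the subject is used, provided it lies within half a period of
#' the tick.
#'
#' @param stream A [frame_stream()], time-sorted.
#' @param period Sampling period in seconds (default 5).
#' @return List of assessments `list(timestamp, subject, skeleton)`,
#'   ordered by subject then time. Empty stream gives an empty list.
#' @export
sample_assessments <- function(stream, period = 5) {
  stopifnot(period > 0)
  frames <- unclass(stream)
  if (length(frames) == 0) return(list())
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  t0 <- min(ts); t1 <- max(ts)
  ticks <- seq(t0, t1, by = period)
  subj_of <- lapply(frames, function(f) {
    vapply(f$skeletons, function(s) s$person_tag, character(1))
  })
  subjects <- sort(unique(unlist(subj_of)))
  out <- list()
  for (subj in subjects) {
    has <- which(vapply(subj_of, function(v) subj %in% v, logical(1)))
    st <- ts[has]
    if (length(st) == 0) next
    # nearest subject-frame per tick (ties to the earlier frame)
    lo <- findInterval(ticks, st)
    d_lo <- ifelse(lo >= 1, ticks - st[pmax(lo, 1L)], Inf)
    d_hi <- ifelse(lo + 1L <= length(st),
                   st[pmin(lo + 1L, length(st))] - ticks, Inf)
    j <- ifelse(d_lo <= d_hi, lo, lo + 1L)
    d <- pmin(d_lo, d_hi)
    keep <- which(d <= period / 2)
    for (ki in keep) {
      fi <- has[j[ki]]
      f <- frames[[fi]]
      skel <- f$skeletons[[match(subj, subj_of[[fi]])]]
      out[[length(out) + 1L]] <- list(timestamp = ticks[ki], subject = subj,
                                      skeleton = skel,
                                      frame_time = f$timestamp)
    }
  }
  out
}

#' Normalized motion score between two skeletons
#'
#' Mean Euclidean displacement over the keypoints detected in both
#' skeletons, divided by the mean torso length of the two; symmetric in
#' its arguments, 0 for identical skeletons and 1.0 for a translation by
#' exactly one torso length. With fewer than 3 commonly detected
#' keypoints the score is undefined (`NA` with attribute
#' `undefined = TRUE`).
#'
#' @param a,b [skeleton()] objects of the same subject.
#' @return Nonnegative score, or flagged `NA`.
#' @export
motion_score <- function(a, b) {
  stopifnot(inherits(a, "skeleton"), inherits(b, "skeleton"))
  common <- detected_keypoints(a) & detected_keypoints(b)
  if (sum(common) < 3) {
    return(structure(NA_real_, undefined = TRUE))
  }
  dx <- a$keypoints$x[common] - b$keypoints$x[common]
  dy <- a$keypoints$y[common] - b$keypoints$y[common]
  disp <- mean(sqrt(dx^2 + dy^2))
  torso_len <- function(s) {
    det <- s$keypoints$confidence >= s$detection_threshold
    sh <- .mid_point2(s$keypoints$x, s$keypoints$y, det,
                      .KP$l_shoulder, .KP$r_shoulder)
    hp <- .mid_point2(s$keypoints$x, s$keypoints$y, det,
                      .KP$l_hip, .KP$r_hip)
    if (anyNA(sh) || anyNA(hp)) NA_real_ else sqrt(sum((sh - hp)^2))
  }
  tl <- c(torso_len(a), torso_len(b))
  tl <- tl[!is.na(tl) & tl > 0]
  if (length(tl) == 0) return(structure(NA_real_, undefined = TRUE))
  disp / mean(tl)
}

#' Build a 3-assessment verification window
#'
#' @param assessments List of exactly three `list(timestamp, subject,
#'   skeleton)` entries spaced by the sampling period.
#' @param static_poses Optional list of pre-computed [classify_static()]
#'   results aligned with `assessments`.
#' @return List of class `assessment_window`.
#' @export
assessment_window <- function(assessments, static_poses = NULL) {
  if (length(assessments) != 3) {
    stop("a verification window requires exactly 3 assessments")
  }
  structure(list(assessments = assessments, static_poses = static_poses),
            class = "assessment_window")
}

#' Verify a pose over a 3-assessment window
#'
#' Majority vote with a severity bias: any 2 of 3 fallen-on-ground
#' assessments yield `fallen_on_ground` immediately; otherwise a >= 2/3
#' majority static class is required, else `undetermined`. A majority of
#' `upright` is split by motion: mean motion score of adjacent assessment
#' pairs above `motion_threshold` means `walking`, else `standing`. A
#' majority of `lying_like` is returned as-is and must be resolved by
#' [disambiguate_lying()]; this function never outputs `sleeping`.
#'
#' @param window An [assessment_window()].
#' @param model Optional `pose_model` for [classify_static()].
#' @param motion_threshold Normalized motion threshold (default 0.05).
#' @param bed_region Optional bed rectangle for feature extraction.
#' @return A single label: one of `walking`, `standing`, `sitting`,
#'   `fallen_on_ground`, `lying_like`, `undetermined`.
#' @export
verify_pose <- function(window, model = NULL, motion_threshold = 0.05,
                        bed_region = NULL) {
  stopifnot(inherits(window, "assessment_window"))
  poses <- window$static_poses
  if (is.null(poses)) {
    poses <- lapply(window$assessments, function(a) {
      classify_static(extract_features(a$skeleton, bed_region = bed_region),
                      model = model)
    })
  }
  values <- vapply(poses, function(p) p$value, character(1))
  if (sum(values == "fallen_on_ground") >= 2) return("fallen_on_ground")
  tab <- table(values[values != "unknown"])
  if (length(tab) == 0 || max(tab) < 2) return("undetermined")
  major <- names(tab)[which.max(tab)]
  if (major == "upright") {
    sk <- lapply(window$assessments, `[[`, "skeleton")
    scores <- c(motion_score(sk[[1]], sk[[2]]), motion_score(sk[[2]], sk[[3]]))
    m <- mean(scores, na.rm = TRUE)
    if (is.nan(m)) return("undetermined")
    return(if (m > motion_threshold) "walking" else "standing")
  }
  major
}

#' Resolve lying-in-bed versus sleeping over a one-minute window
#'
#' After at least 60 s of continuous lying-like assessments the label is
#' refined using the wristband: `sleeping` iff the band reports sleep
#' state for the majority of the window, or the subject is essentially
#' still (mean motion below `still_threshold`) with a heart rate at least
#' `hr_margin` bpm below the personal awake baseline; otherwise
#' `lying_in_bed`. With no usable vitals in the window the decision falls
#' back to motion alone and the result carries a `low_confidence`
#' attribute.
#'
#' @param assessments List of lying-like assessments covering >= 60 s.
#' @param vitals A [vitals_series()] (LOCF-filled) covering the window.
#' @param baseline_hr Personal awake heart-rate baseline in bpm.
#' @param still_threshold Normalized motion below which the subject counts
#'   as still (default 0.02).
#' @param hr_margin Required heart-rate drop below baseline, bpm
#'   (default 10).
#' @return `"sleeping"` or `"lying_in_bed"` (possibly with attribute
#'   `low_confidence = TRUE`).
#' @export
disambiguate_lying <- function(assessments, vitals, baseline_hr,
                               still_threshold = 0.02, hr_margin = 10) {
  ts <- vapply(assessments, function(a) a$timestamp, numeric(1))
  if (length(assessments) < 2 || diff(range(ts)) < 55) {
    stop("disambiguation requires >= 60 s of lying-like assessments")
  }
  scores <- vapply(seq_len(length(assessments) - 1), function(i) {
    as.numeric(motion_score(assessments[[i]]$skeleton,
                            assessments[[i + 1]]$skeleton))
  }, numeric(1))
  motion <- mean(scores, na.rm = TRUE)
  still <- !is.nan(motion) && motion < still_threshold

  w0 <- min(ts); w1 <- max(ts)
  in_win <- !is.na(vitals$timestamp) & vitals$timestamp >= w0 &
    vitals$timestamp <= w1
  sleep_flags <- vitals$sleep_state[in_win]
  hr <- vitals$heart_rate[in_win]
  have_sleep <- any(!is.na(sleep_flags))
  have_hr <- any(!is.na(hr))

  if (!have_sleep && !have_hr) {
    label <- if (still) "sleeping" else "lying_in_bed"
    return(structure(label, low_confidence = TRUE))
  }
  band_asleep <- have_sleep && mean(sleep_flags, na.rm = TRUE) >= 0.5
  hr_low <- have_hr && mean(hr, na.rm = TRUE) <= baseline_hr - hr_margin
  if (band_asleep || (still && hr_low)) "sleeping" else "lying_in_bed"
}

#' Personal awake heart-rate baseline
#'
#' Trailing median of heart-rate observations taken while the band does
#' not report sleep, over a trailing window (default 7 days) ending at
#' `at`. Falls back to the median of all heart-rate observations, then to
#' 70 bpm, when no awake samples exist.
#'
#' @param vitals A [vitals_series()].
#' @param at Reference time (POSIX seconds); default end of series.
#' @param window_days Trailing window length in days.
#' @return Baseline heart rate in bpm.
#' @export
baseline_heart_rate <- function(vitals, at = NULL, window_days = 7) {
  if (nrow(vitals) == 0) return(70)
  at <- at %||% max(vitals$timestamp)
  recent <- vitals$timestamp >= at - window_days * 86400 &
    vitals$timestamp <= at
  awake <- recent & !is.na(vitals$heart_rate) &
    (is.na(vitals$sleep_state) | !vitals$sleep_state)
  if (any(awake)) return(stats::median(vitals$heart_rate[awake]))
  hr <- vitals$heart_rate[recent & !is.na(vitals$heart_rate)]
  if (length(hr)) stats::median(hr) else 70
}

#' Monitoring configuration
#'
#' @param period Assessment sampling period, seconds.
#' @param motion_threshold Walking/standing motion split (normalized).
#' @param still_threshold Stillness bound for sleep inference (normalized).
#' @param hr_margin Heart-rate drop below baseline required for sleep, bpm.
#' @param bed_region Bed rectangle `c(x_min, y_min, x_max, y_max)` pixels.
#' @param max_inherit_minutes Undetermined minutes inherit the previous
#'   verified pose up to this cap.
#' @param tz Timezone for calendar-day bucketing of the ledger.
#' @return List of class `monitor_config`.
#' @export
monitor_config <- function(period = 5, motion_threshold = 0.05,
                           still_threshold = 0.02, hr_margin = 10,
                           bed_region = NULL, max_inherit_minutes = 5,
                           tz = "UTC") {
  stopifnot(period > 0, motion_threshold > 0, still_threshold > 0,
            hr_margin > 0, max_inherit_minutes >= 0)
  structure(list(period = period, motion_threshold = motion_threshold,
                 still_threshold = still_threshold, hr_margin = hr_margin,
                 bed_region = bed_region,
                 max_inherit_minutes = max_inherit_minutes, tz = tz),
            class = "monitor_config")
}

.empty_ledger <- function() {
  cols <- c("subject", "day", pose_labels())
  df <- as.data.frame(stats::setNames(
    c(list(character(0), as.Date(character(0))),
      rep(list(numeric(0)), 6)), cols))
  class(df) <- c("activity_ledger", "data.frame")
  df
}

#' Build an activity ledger from per-minute labels
#'
#' Hours per calendar day in each of the six pose labels; labelled minutes
#' divided by 60. Per-day totals can never exceed 24 h.
#'
#' @param labels Data frame with columns `minute` (POSIX seconds of minute
#'   start), `subject`, `pose`.
#' @param tz Timezone used to assign minutes to calendar days.
#' @return Data frame of class `activity_ledger` with one row per
#'   (subject, day) and one hours column per pose.
#' @export
activity_ledger <- function(labels, tz = "UTC") {
  if (nrow(labels) == 0) return(.empty_ledger())
  labels <- labels[labels$pose %in% pose_labels(), , drop = FALSE]
  if (nrow(labels) == 0) return(.empty_ledger())
  day <- as.Date(as.POSIXct(labels$minute, origin = "1970-01-01", tz = tz),
                 tz = tz)
  agg <- stats::aggregate(list(minutes = rep(1, nrow(labels))),
                          by = list(subject = labels$subject, day = day,
                                    pose = labels$pose), FUN = sum)
  keys <- unique(agg[, c("subject", "day")])
  out <- keys
  for (p in pose_labels()) out[[p]] <- 0
  for (i in seq_len(nrow(agg))) {
    j <- which(out$subject == agg$subject[i] & out$day == agg$day[i])
    out[j, agg$pose[i]] <- agg$minutes[i] / 60
  }
  out <- out[order(out$subject, out$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("activity_ledger", "data.frame")
  out
}

#' Run the minute-level monitoring protocol
#'
#' For every subject and every minute of the stream: sample assessments
#' every `period` seconds, classify each statically, verify the first
#' three assessments of the minute (15 s window), split a lying-like
#' verdict with the full minute of assessments plus LOCF-filled wristband
#' vitals, and emit one final pose label per subject-minute. Undetermined
#' minutes inherit the previous verified pose for at most
#' `max_inherit_minutes` minutes; a subject absent for a full minute
#' yields a gap, not an error. An alert event is emitted on each
#' transition into `fallen_on_ground`.
#'
#' @param stream A [frame_stream()].
#' @param vitals A [vitals_series()] (or `NULL`).
#' @param model Optional `pose_model`; `NULL` selects the rule fallback.
#' @param config A [monitor_config()].
#' @return List of class `monitor_result`: `labels` (data frame `minute,
#'   subject, pose, confidence, alert`), `ledger` (an
#'   [activity_ledger()]), and `alerts`.
#' @export
monitor <- function(stream, vitals = NULL, model = NULL,
                    config = monitor_config()) {
  stopifnot(inherits(config, "monitor_config"))
  if (is.null(vitals)) {
    vitals <- vitals_series(data.frame(timestamp = numeric(0)))
  }
  for (f in c("heart_rate", "sleep_state")) {
    vitals <- locf_fill(vitals, f)
  }
  assessments <- sample_assessments(stream, period = config$period)
  rows <- list()
  alerts <- list()
  if (length(assessments) > 0) {
    subj <- vapply(assessments, `[[`, character(1), "subject")
    ats <- vapply(assessments, `[[`, numeric(1), "timestamp")
    for (s in unique(subj)) {
      sel <- which(subj == s)
      sel <- sel[order(ats[sel])]
      a_list <- assessments[sel]
      a_ts <- ats[sel]
      statics <- lapply(a_list, function(a) {
        classify_static(extract_features(a$skeleton,
                                         bed_region = config$bed_region),
                        model = model)
      })
      minutes <- seq(floor(min(a_ts) / 60) * 60, max(a_ts), by = 60)
      prev_pose <- NA_character_
      inherit_left <- 0L
      in_fall <- FALSE
      base_hr <- baseline_heart_rate(vitals)
      for (m in minutes) {
        win_idx <- which(a_ts >= m & a_ts < m + 3 * config$period)
        label <- "undetermined"
        conf <- NA_real_
        if (length(win_idx) >= 3) {
          win_idx <- win_idx[1:3]
          w <- assessment_window(a_list[win_idx], statics[win_idx])
          label <- verify_pose(w, model = model,
                               motion_threshold = config$motion_threshold,
                               bed_region = config$bed_region)
          conf <- mean(vapply(statics[win_idx], function(p) p$confidence,
                              numeric(1)))
          if (label == "lying_like") {
            min_idx <- which(a_ts >= m & a_ts < m + 60)
            lying_frac <- mean(vapply(statics[min_idx], function(p)
              p$value == "lying_like", logical(1)))
            if (length(min_idx) >= 2 &&
                diff(range(a_ts[min_idx])) >= 55 && lying_frac >= 0.8) {
              label <- disambiguate_lying(
                a_list[min_idx], vitals, baseline_hr = base_hr,
                still_threshold = config$still_threshold,
                hr_margin = config$hr_margin)
              label <- as.character(label)
            } else {
              label <- "lying_in_bed"
            }
          }
        }
        if (label == "undetermined") {
          if (!is.na(prev_pose) && inherit_left > 0L) {
            label <- prev_pose
            inherit_left <- inherit_left - 1L
          }
        } else {
          prev_pose <- label
          inherit_left <- as.integer(config$max_inherit_minutes)
        }
        alert <- FALSE
        if (label == "fallen_on_ground" && !in_fall) {
          alert <- TRUE
          alerts[[length(alerts) + 1L]] <-
            data.frame(minute = m, subject = s, event = "fallen_on_ground")
        }
        in_fall <- identical(label, "fallen_on_ground")
        if (label != "undetermined") {
          rows[[length(rows) + 1L]] <-
            data.frame(minute = m, subject = s, pose = label,
                       confidence = conf, alert = alert)
        }
      }
    }
  }
  labels <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(minute = numeric(0), subject = character(0),
               pose = character(0), confidence = numeric(0),
               alert = logical(0))
  }
  structure(list(labels = labels,
                 ledger = activity_ledger(labels, tz = config$tz),
                 alerts = if (length(alerts)) do.call(rbind, alerts) else
                   data.frame(minute = numeric(0), subject = character(0),
                              event = character(0))),
            class = "monitor_result")
}

#' @export
print.monitor_result <- function(x, ...) {
  cat(sprintf("<monitor_result> %d labelled minutes, %d alert(s), %d ledger day(s)\n",
              nrow(x$labels), nrow(x$alerts), nrow(x$ledger)))
  invisible(x)
}
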