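#' Construct a single-person skeleton
#'
#' A skeleton is one person's 17 keypoints observed in one frame. Keypoints
#' with confidence below the detection threshold are treated as undetected
#' and their coordinates are ignored by all downstream geometry.
#'
#' Coordinates are image pixels with the origin at the top-left corner,
#' x increasing rightward and y increasing downward (0-based).
#'
#' @param keypoints Data frame with columns `name`, `x`, `y`, `confidence`;
#'   exactly 17 rows in canonical order (see [keypoint_names()]).
#' @param timestamp Time of observation in POSIX seconds.
#' @param person_tag Identity label, or `"unknown"`.
#' @param bbox Numeric `c(x_min, y_min, x_max, y_max)`; computed from the
#'   detected keypoints when `NULL`.
#' @param detection_threshold Confidence below which a keypoint is
#'   undetected.
#' @return An object of class `skeleton`.
#' @export
skeleton <- function(keypoints, timestamp, person_tag = "unknown",
                     bbox = NULL,
                     detection_threshold = DEFAULT_DETECTION_THRESHOLD) {
  stopifnot(is.data.frame(keypoints))
  required <- c("name", "x", "y", "confidence")
  missing_cols <- setdiff(required, names(keypoints))
  if (length(missing_cols) > 0) {
    stop("keypoints is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(keypoints) != 17L) {
    stop("a skeleton requires exactly 17 keypoints, got ", nrow(keypoints))
  }
  if (!identical(as.character(keypoints$name), keypoint_names())) {
    bad <- setdiff(keypoint_names(), as.character(keypoints$name))
    stop("keypoints not in canonical order; missing or misplaced landmark(s): ",
         paste(if (length(bad)) bad else "order mismatch", collapse = ", "))
  }
  if (any(keypoints$confidence < 0 | keypoints$confidence > 1, na.rm = TRUE)) {
    stop("keypoint confidence must lie in [0, 1]")
  }
  # lightweight data.frame construction; this runs once per person-frame
  kp <- structure(list(name = keypoint_names(),
                       x = as.numeric(keypoints$x),
                       y = as.numeric(keypoints$y),
                       confidence = as.numeric(keypoints$confidence)),
                  class = "data.frame", row.names = 1:17)
  det <- kp$confidence >= detection_threshold
  if (is.null(bbox)) {
    if (any(det)) {
      bbox <- c(min(kp$x[det]), min(kp$y[det]), max(kp$x[det]), max(kp$y[det]))
    } else {
      bbox <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    }
  }
  structure(list(person_tag = person_tag,
                 timestamp = as.numeric(timestamp),
                 keypoints = kp,
                 bbox = as.numeric(bbox),
                 detection_threshold = detection_threshold),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  n_det <- sum(detected_keypoints(x))
  cat(sprintf("<skeleton> person=%s t=%.2f detected=%d/17\n",
              x$person_tag, x$timestamp, n_det))
  invisible(x)
}

#' Which keypoints of a skeleton are detected?
#'
#' @param skel A [skeleton()].
#' @param threshold Optional confidence threshold overriding the skeleton's.
#' @return Logical vector of length 17, named by landmark.
#' @export
detected_keypoints <- function(skel, threshold = NULL) {
  thr <- threshold %||% skel$detection_threshold
  out <- skel$keypoints$confidence >= thr
  names(out) <- skel$keypoints$name
  out
}

#' Construct a frame record
#'
#' One camera frame: a timestamp, zero or more skeletons, and an ambient
#' lighting tag. The lighting tag is metadata only; it never alters any
#' geometry.
#'
#' @param timestamp POSIX seconds.
#' @param skeletons List of [skeleton()] objects (possibly empty).
#' @param lighting One of `"well_lit"`, `"semi_lit"`, `"poorly_lit"`.
#' @return An object of class `frame_record`.
#' @export
frame_record <- function(timestamp, skeletons = list(), lighting = "well_lit") {
  lighting <- match.arg(lighting, lighting_tags())
  stopifnot(all(vapply(skeletons, inherits, logical(1), "skeleton")))
  structure(list(timestamp = as.numeric(timestamp),
                 skeletons = skeletons,
                 lighting = lighting),
            class = "frame_record")
}

#' Assemble frames into a skeleton stream
#'
#' @param frames List of [frame_record()] objects; sorted by timestamp.
#' @return An object of class `frame_stream` (a list of frames).
#' @export
frame_stream <- function(frames = list()) {
  stopifnot(all(vapply(frames, inherits, logical(1), "frame_record")))
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (length(ts) > 1 && is.unsorted(ts)) {
    frames <- frames[order(ts)]
  }
  structure(frames, class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  ts <- vapply(unclass(x), function(f) f$timestamp, numeric(1))
  cat(sprintf("<frame_stream> %d frames", length(x)))
  if (length(x)) cat(sprintf(" spanning [%.2f, %.2f] s", min(ts), max(ts)))
  cat("\n")
  invisible(x)
}

# flatten one skeleton into the 51-float keypoint layout (x, y, conf) * 17
.skeleton_to_flat <- function(skel) {
  as.numeric(t(as.matrix(skel$keypoints[, c("x", "y", "confidence")])))
}

.flat_to_keypoints <- function(v) {
  if (length(v) != 51) stop("keypoint vector must hold 51 values (17 x 3)")
  m <- matrix(as.numeric(v), ncol = 3, byrow = TRUE)
  data.frame(name = keypoint_names(), x = m[, 1], y = m[, 2],
             confidence = m[, 3], stringsAsFactors = FALSE)
}

#' Write a skeleton stream to disk
#'
#' Two formats are supported. `keypoint_json` is a COCO-keypoint-style JSON
#' document: a `frames` index (timestamp + lighting, so frames with no
#' detected person survive a round trip) and an `annotations` list of
#' `{timestamp, person, keypoints (51 floats), bbox}` entries. `csv` writes
#' one row per (frame, person) with `kp_<landmark>_{x,y,c}` columns; a frame
#' with no skeletons becomes a row with an empty person cell.
#'
#' @param stream A [frame_stream()].
#' @param path Output file path.
#' @param format `"keypoint_json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_skeleton_stream <- function(stream, path,
                                  format = c("keypoint_json", "csv")) {
  format <- match.arg(format)
  frames <- unclass(stream)
  if (format == "keypoint_json") {
    frames_idx <- lapply(frames, function(f) {
      list(timestamp = f$timestamp, lighting = f$lighting)
    })
    ann <- list()
    for (f in frames) {
      for (s in f$skeletons) {
        ann[[length(ann) + 1L]] <- list(
          timestamp = f$timestamp,
          person = s$person_tag,
          keypoints = .skeleton_to_flat(s),
          bbox = s$bbox)
      }
    }
    jsonlite::write_json(list(frames = frames_idx, annotations = ann), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    kp_cols <- as.vector(t(outer(keypoint_names(), c("x", "y", "c"),
                                 function(a, b) paste0("kp_", a, "_", b))))
    rows <- list()
    for (f in frames) {
      if (length(f$skeletons) == 0) {
        row <- c(list(timestamp = f$timestamp, person = NA_character_,
                      lighting = f$lighting,
                      bbox_xmin = NA_real_, bbox_ymin = NA_real_,
                      bbox_xmax = NA_real_, bbox_ymax = NA_real_),
                 stats::setNames(as.list(rep(NA_real_, 51)), kp_cols))
        rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
      } else {
        for (s in f$skeletons) {
          row <- c(list(timestamp = f$timestamp, person = s$person_tag,
                        lighting = f$lighting,
                        bbox_xmin = s$bbox[1], bbox_ymin = s$bbox[2],
                        bbox_xmax = s$bbox[3], bbox_ymax = s$bbox[4]),
                   stats::setNames(as.list(.skeleton_to_flat(s)), kp_cols))
          rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
        }
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else {
      as.data.frame(stats::setNames(
        rep(list(numeric(0)), 7 + 51),
        c("timestamp", "person", "lighting", "bbox_xmin", "bbox_ymin",
          "bbox_xmax", "bbox_ymax", kp_cols)))
    }
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a skeleton stream
#'
#' Inverse of [write_skeleton_stream()]. Frames are returned sorted by
#' timestamp; malformed rows are reported with their position, and missing
#' keypoint columns are reported by landmark name.
#'
#' @param path Input file path.
#' @param format `"keypoint_json"` or `"csv"`.
#' @param strict When `TRUE`, non-monotone timestamps in the file raise an
#'   ordering error instead of being sorted silently.
#' @return A [frame_stream()].
#' @export
read_skeleton_stream <- function(path, format = c("keypoint_json", "csv"),
                                 strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "keypoint_json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    frames_idx <- doc$frames %||% list()
    ann <- doc$annotations %||% list()
    ts_idx <- vapply(frames_idx, function(f) as.numeric(f$timestamp), numeric(1))
    if (strict && length(ts_idx) > 1 && is.unsorted(ts_idx, strictly = FALSE)) {
      stop("ordering error: frame timestamps are not non-decreasing")
    }
    frames <- lapply(frames_idx, function(f) {
      frame_record(as.numeric(f$timestamp), list(),
                   lighting = f$lighting %||% "well_lit")
    })
    key <- vapply(frames, function(f) sprintf("%.9f", f$timestamp), character(1))
    for (i in seq_along(ann)) {
      a <- ann[[i]]
      kpv <- unlist(a$keypoints)
      if (length(kpv) != 51) {
        stop(sprintf("format error at annotation %d: expected 51 keypoint values, got %d",
                     i, length(kpv)))
      }
      sk <- skeleton(.flat_to_keypoints(kpv), as.numeric(a$timestamp),
                     person_tag = a$person %||% "unknown",
                     bbox = if (!is.null(a$bbox)) unlist(a$bbox) else NULL)
      j <- match(sprintf("%.9f", sk$timestamp), key)
      if (is.na(j)) {
        frames[[length(frames) + 1L]] <- frame_record(sk$timestamp, list(sk))
        key <- c(key, sprintf("%.9f", sk$timestamp))
      } else {
        frames[[j]]$skeletons <- c(frames[[j]]$skeletons, list(sk))
      }
    }
    return(frame_stream(frames))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kp_cols <- as.vector(t(outer(keypoint_names(), c("x", "y", "c"),
                               function(a, b) paste0("kp_", a, "_", b))))
  missing_cols <- setdiff(kp_cols, names(df))
  if (length(missing_cols) > 0) {
    landmarks <- unique(sub("^kp_(.*)_[xyc]$", "\\1", missing_cols))
    stop("format error: missing keypoint column(s) for landmark(s): ",
         paste(landmarks, collapse = ", "))
  }
  if (strict && nrow(df) > 1 && is.unsorted(df$timestamp)) {
    stop("ordering error: timestamps are not non-decreasing")
  }
  frames <- list()
  key <- character(0)
  for (i in seq_len(nrow(df))) {
    ts <- df$timestamp[i]
    if (is.na(ts)) stop(sprintf("format error at row %d: missing timestamp", i))
    k <- sprintf("%.9f", ts)
    j <- match(k, key)
    if (is.na(j)) {
      frames[[length(frames) + 1L]] <-
        frame_record(ts, list(), lighting = df$lighting[i] %||% "well_lit")
      key <- c(key, k)
      j <- length(frames)
    }
    person <- df$person[i]
    if (!is.na(person) && nzchar(person)) {
      kpv <- as.numeric(df[i, kp_cols])
      if (anyNA(kpv)) {
        stop(sprintf("format error at row %d: incomplete keypoint values", i))
      }
      bbox <- as.numeric(df[i, c("bbox_xmin", "bbox_ymin", "bbox_xmax", "bbox_ymax")])
      if (anyNA(bbox)) bbox <- NULL
      sk <- skeleton(.flat_to_keypoints(kpv), ts, person_tag = person, bbox = bbox)
      frames[[j]]$skeletons <- c(frames[[j]]$skeletons, list(sk))
    }
  }
  frame_stream(frames)
}

# ---- vitals -----------------------------------------------------------------

.vitals_numeric_fields <- c("heart_rate", "spo2", "systolic", "diastolic",
                            "weight", "sleep_hours")
.vitals_fields <- c(.vitals_numeric_fields, "sleep_state")

#' Construct a vitals series
#'
#' Timestamped wearable/device measurements. Missing values are `NA`;
#' last-observation-carried-forward semantics are applied explicitly with
#' [locf_fill()], never implicitly.
#'
#' @param df Data frame with columns `timestamp`, `heart_rate`, `spo2`,
#'   `systolic`, `diastolic`, `weight`, `sleep_state` (logical),
#'   `sleep_hours`, `source`. Missing columns are filled with `NA`.
#' @return A data frame of class `vitals_series`, sorted by timestamp.
#' @export
vitals_series <- function(df) {
  stopifnot(is.data.frame(df), "timestamp" %in% names(df))
  for (f in .vitals_numeric_fields) {
    if (!f %in% names(df)) df[[f]] <- rep(NA_real_, nrow(df))
    df[[f]] <- as.numeric(df[[f]])
  }
  if (!"sleep_state" %in% names(df)) df$sleep_state <- rep(NA, nrow(df))
  df$sleep_state <- as.logical(df$sleep_state)
  if (!"source" %in% names(df)) df$source <- rep(NA_character_, nrow(df))
  df <- df[order(df$timestamp),
           c("timestamp", "heart_rate", "spo2", "systolic", "diastolic",
             "weight", "sleep_state", "sleep_hours", "source")]
  bad_pos <- vapply(.vitals_numeric_fields, function(f) {
    any(df[[f]] <= 0, na.rm = TRUE) && f != "sleep_hours"
  }, logical(1))
  if (any(bad_pos)) {
    stop("non-positive values in field(s): ",
         paste(.vitals_numeric_fields[bad_pos], collapse = ", "))
  }
  if (any(df$sleep_hours < 0 | df$sleep_hours > 24, na.rm = TRUE)) {
    stop("sleep_hours must lie in [0, 24]")
  }
  rownames(df) <- NULL
  class(df) <- c("vitals_series", "data.frame")
  df
}

#' Read a vitals CSV
#'
#' Expects the header `timestamp,heart_rate,spo2,systolic,diastolic,weight,
#' sleep_state,sleep_hours,source`; an empty cell means missing.
#'
#' @param path CSV path.
#' @return A [vitals_series()].
#' @export
read_vitals_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  vitals_series(df)
}

#' Write a vitals series to CSV
#'
#' @param series A [vitals_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vitals_csv <- function(series, path) {
  df <- as.data.frame(series)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Carry the last observation forward over missing vitals
#'
#' Replaces each missing value of `field` with the most recent observed
#' value, provided that observation is no older than `max_staleness`
#' seconds; older gaps remain missing. Observed values are never changed,
#' and the operation is idempotent.
#'
#' @param series A [vitals_series()], sorted by timestamp.
#' @param field One of the vitals field names (e.g. `"heart_rate"`,
#'   `"sleep_state"`).
#' @param max_staleness Maximum age, in seconds, of a carried-forward value.
#'   Defaults to 24 hours; a bound prevents silently stale vitals.
#' @return The series with `field` filled. The positions of the original
#'   observations are recorded in the attribute `locf_observed`, so that
#'   re-applying the fill measures staleness from true observations (the
#'   operation is idempotent, and carried values never age-reset the
#'   staleness clock).
#' @export
locf_fill <- function(series, field, max_staleness = 86400) {
  if (!field %in% .vitals_fields) {
    stop("unknown vitals field: ", field,
         " (expected one of: ", paste(.vitals_fields, collapse = ", "), ")")
  }
  stopifnot(max_staleness >= 0)
  v <- series[[field]]
  ts <- series$timestamp
  masks <- attr(series, "locf_observed")
  observed <- masks[[field]]
  if (is.null(observed) || length(observed) != length(v)) {
    observed <- !is.na(v)
  }
  last_val <- NA
  last_ts <- -Inf
  for (i in seq_along(v)) {
    if (observed[i] && !is.na(v[i])) {
      last_val <- v[i]
      last_ts <- ts[i]
    } else if (!is.na(last_val) && (ts[i] - last_ts) <= max_staleness) {
      v[i] <- last_val
    } else {
      v[i] <- NA
    }
  }
  series[[field]] <- v
  masks[[field]] <- observed
  attr(series, "locf_observed") <- masks
  series
}
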