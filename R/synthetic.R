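#' @name synthetic
#' @title Synthetic ward data generators
#' @description
#' Deterministic, seeded generators for every input the pipeline
#' consumes: articulated 2D skeleton streams per pose, wristband vitals
#' series, schema-valid patient states labelled by the rule engine, and
#' procedurally textured ward images for re-identification. Every
#' generator is a pure function of its script/parameters and seed, and
#' emits ground truth alongside the data.
NULL

#' Scenario script for the skeleton and vitals generators
#'
#' @param segments Data frame `start, end, pose, amplitude` (seconds,
#'   seconds, pose label, motion amplitude in torso lengths per second);
#'   segments must not overlap. Poses are the six final labels.
#' @param subject Subject tag.
#' @param fps Frame rate of the generated stream (default 10).
#' @param baseline_hr Awake heart-rate baseline, bpm.
#' @param sleep_hr_drop Scripted heart-rate reduction while asleep, bpm.
#' @param sleep_intervals Data frame `start, end` of scripted sleep.
#' @param noise_sd Keypoint noise standard deviation, as a fraction of
#'   torso length.
#' @param occlusion_prob Per-keypoint dropout probability.
#' @param torso_px Torso length in pixels on the synthetic canvas.
#' @param canvas `c(width, height)` pixels.
#' @param bed_region Bed rectangle `c(x_min, y_min, x_max, y_max)`.
#' @param lighting Lighting tag applied to all frames.
#' @param seed RNG seed; together with the script it fully determines the
#'   output.
#' @return List of class `scenario_script`.
#' @export
scenario_script <- function(segments, subject = "patient1", fps = 10,
                            baseline_hr = 70, sleep_hr_drop = 15,
                            sleep_intervals = NULL, noise_sd = 0,
                            occlusion_prob = 0, torso_px = 80,
                            canvas = c(640, 480),
                            bed_region = c(420, 220, 630, 400),
                            lighting = "well_lit", seed = 1) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "pose") %in% names(segments)))
  if (!"amplitude" %in% names(segments)) segments$amplitude <- 0.6
  if (any(segments$end <= segments$start)) {
    stop("invalid script: segment end must exceed start")
  }
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1 &&
      any(segments$start[-1] < segments$end[-nrow(segments)] - 1e-9)) {
    stop("invalid script: segments overlap")
  }
  bad <- setdiff(segments$pose, pose_labels())
  if (length(bad)) stop("invalid script: unknown pose(s) ",
                        paste(bad, collapse = ", "))
  structure(list(segments = segments, subject = subject, fps = fps,
                 baseline_hr = baseline_hr, sleep_hr_drop = sleep_hr_drop,
                 sleep_intervals = sleep_intervals, noise_sd = noise_sd,
                 occlusion_prob = occlusion_prob, torso_px = torso_px,
                 canvas = canvas, bed_region = bed_region,
                 lighting = lighting, seed = seed),
            class = "scenario_script")
}

# canonical stick-figure keypoints in body units (torso length 1),
# origin at mid-hip, x rightward, y downward (standing)
.base_pose_standing <- function(phase = 0, swing = 0) {
  sw <- swing * sin(phase)
  m <- rbind(
    nose = c(0, -1.25),
    left_eye = c(-0.04, -1.30), right_eye = c(0.04, -1.30),
    left_ear = c(-0.08, -1.28), right_ear = c(0.08, -1.28),
    left_shoulder = c(-0.12, -1.0), right_shoulder = c(0.12, -1.0),
    left_elbow = c(-0.16 - sw * 0.5, -0.55),
    right_elbow = c(0.16 + sw * 0.5, -0.55),
    left_wrist = c(-0.18 - sw, -0.10), right_wrist = c(0.18 + sw, -0.10),
    left_hip = c(-0.10, 0), right_hip = c(0.10, 0),
    left_knee = c(-0.11 + sw, 0.55), right_knee = c(0.11 - sw, 0.55),
    left_ankle = c(-0.12 + sw * 1.6, 1.10), right_ankle = c(0.12 - sw * 1.6, 1.10))
  m
}

.base_pose_sitting <- function() {
  rbind(
    nose = c(0, -1.25),
    left_eye = c(-0.04, -1.30), right_eye = c(0.04, -1.30),
    left_ear = c(-0.08, -1.28), right_ear = c(0.08, -1.28),
    left_shoulder = c(-0.12, -1.0), right_shoulder = c(0.12, -1.0),
    left_elbow = c(-0.14, -0.55), right_elbow = c(0.14, -0.55),
    left_wrist = c(0.20, -0.30), right_wrist = c(0.24, -0.30),
    left_hip = c(-0.10, 0), right_hip = c(0.10, 0),
    left_knee = c(0.45, 0.05), right_knee = c(0.50, 0.05),
    left_ankle = c(0.45, 0.60), right_ankle = c(0.50, 0.60))
}

# lying poses: the standing figure rotated 90 degrees (head to the left)
.base_pose_lying <- function() {
  m <- .base_pose_standing()
  cbind(m[, 2], -m[, 1] * 0.4)   # x = body axis, y flattened
}

.pose_keypoints <- function(pose, t, seg_start, amplitude, script) {
  s <- script$torso_px
  cw <- script$canvas[1]; ch <- script$canvas[2]
  bed <- script$bed_region
  if (pose %in% c("standing", "walking")) {
    phase <- 2 * pi * 1.5 * (t - seg_start)
    swing <- if (pose == "walking") 0.15 else 0
    m <- .base_pose_standing(phase, swing)
    x0 <- if (pose == "walking") {
      20 + ((t - seg_start) * amplitude * s) %% (cw * 0.5 - 40)
    } else cw * 0.25
    origin <- c(x0, ch * 0.55)
  } else if (pose == "sitting") {
    m <- .base_pose_sitting()
    origin <- c(cw * 0.25, ch * 0.60)
  } else if (pose %in% c("lying_in_bed", "sleeping")) {
    m <- .base_pose_lying()
    origin <- c((bed[1] + bed[3]) / 2, (bed[2] + bed[4]) / 2)
    if (pose == "lying_in_bed" && amplitude > 0) {
      # restless micro-motion: small positional sway
      origin <- origin + c(sin(2 * pi * 0.4 * t), cos(2 * pi * 0.3 * t)) *
        amplitude * s
    }
  } else if (pose == "fallen_on_ground") {
    m <- .base_pose_lying()
    origin <- c(cw * 0.20, ch * 0.90)
  } else {
    stop("unsupported pose: ", pose)
  }
  sweep(m * s, 2, origin, `+`)
}

#' Generate an articulated skeleton stream from a scenario script
#'
#' One frame per `1/fps` seconds within each scripted segment. Standing is
#' a vertical stick figure; walking adds horizontal translation and limb
#' oscillation; sitting flexes the knees to about 90 degrees; lying and
#' sleeping are horizontal figures inside the bed region (sleeping with
#' near-zero motion); fallen-on-ground is a horizontal figure on the
#' floor, outside the bed. Isotropic Gaussian keypoint noise and
#' per-keypoint occlusion dropout follow the script. Ground-truth labels
#' are attached as attribute `truth`.
#'
#' @param script A [scenario_script()].
#' @param fps Frames per second (defaults to the script's).
#' @return A [frame_stream()] with attribute `truth` (data frame
#'   `timestamp, pose`).
#' @export
generate_skeleton_sequence <- function(script, fps = NULL) {
  stopifnot(inherits(script, "scenario_script"))
  fps <- fps %||% script$fps
  set.seed(script$seed)
  seg_times <- lapply(seq_len(nrow(script$segments)), function(i) {
    seq(script$segments$start[i], script$segments$end[i] - 1e-9, by = 1 / fps)
  })
  n_total <- sum(lengths(seg_times))
  frames <- vector("list", n_total)
  truth_ts <- numeric(n_total)
  truth_pose <- character(n_total)
  pos <- 0L
  for (i in seq_len(nrow(script$segments))) {
    seg <- script$segments[i, ]
    for (t in seg_times[[i]]) {
      m <- .pose_keypoints(seg$pose, t, seg$start, seg$amplitude, script)
      if (script$noise_sd > 0) {
        m <- m + matrix(stats::rnorm(34, 0, script$noise_sd * script$torso_px),
                        17, 2)
      }
      conf <- rep(0.95, 17)
      if (script$occlusion_prob > 0) {
        conf[stats::runif(17) < script$occlusion_prob] <- 0
      }
      kp <- data.frame(name = keypoint_names(), x = m[, 1], y = m[, 2],
                       confidence = conf, stringsAsFactors = FALSE)
      sk <- skeleton(kp, t, person_tag = script$subject)
      pos <- pos + 1L
      frames[[pos]] <- frame_record(t, list(sk), lighting = script$lighting)
      truth_ts[pos] <- t
      truth_pose[pos] <- seg$pose
    }
  }
  out <- frame_stream(frames)
  attr(out, "truth") <- data.frame(timestamp = truth_ts, pose = truth_pose,
                                   stringsAsFactors = FALSE)
  out
}

#' Generate a wristband vitals series from a scenario script
#'
#' Heart rate is the scripted baseline plus a small circadian sine and
#' Gaussian noise, reduced by `sleep_hr_drop` bpm inside scripted sleep
#' intervals where `sleep_state` is `TRUE`. Scripted dropouts blank
#' individual measurements for carry-forward testing.
#'
#' @param script A [scenario_script()].
#' @param sample_interval Seconds between samples (default 60).
#' @param dropout_prob Probability that a sample's measurement fields are
#'   missing.
#' @return A [vitals_series()].
#' @export
generate_vitals <- function(script, sample_interval = 60, dropout_prob = 0) {
  stopifnot(inherits(script, "scenario_script"))
  if (script$baseline_hr <= 0) stop("baseline heart rate must be positive")
  set.seed(script$seed + 1)
  t0 <- min(script$segments$start)
  t1 <- max(script$segments$end)
  ts <- seq(t0, t1, by = sample_interval)
  asleep <- rep(FALSE, length(ts))
  si <- script$sleep_intervals
  if (!is.null(si)) {
    for (i in seq_len(nrow(si))) {
      asleep <- asleep | (ts >= si$start[i] & ts < si$end[i])
    }
  }
  hr <- script$baseline_hr +
    4 * sin(2 * pi * ((ts %% 86400) / 86400) - pi / 2) +
    stats::rnorm(length(ts), 0, 1.5)
  hr[asleep] <- hr[asleep] - script$sleep_hr_drop
  spo2 <- pmin(100, 97 + stats::rnorm(length(ts), 0, 0.8))
  sys <- 125 + stats::rnorm(length(ts), 0, 4)
  dia <- 78 + stats::rnorm(length(ts), 0, 3)
  wt <- 72 + stats::rnorm(length(ts), 0, 0.1)
  df <- data.frame(timestamp = ts, heart_rate = hr, spo2 = spo2,
                   systolic = sys, diastolic = dia, weight = wt,
                   sleep_state = asleep, sleep_hours = NA_real_,
                   source = "synthetic_band")
  if (dropout_prob > 0) {
    drop <- stats::runif(length(ts)) < dropout_prob
    for (f in c("heart_rate", "spo2", "systolic", "diastolic", "weight",
                "sleep_state")) {
      df[[f]][drop] <- NA
    }
  }
  vitals_series(df)
}

#' Generate rule-labelled synthetic patient states
#'
#' States are sampled independently per variable — uniformly from each
#' value set, or under supplied priors — and labelled by
#' [evaluate_rules()]: the rule engine is the ground-truth oracle for
#' decision-tree training.
#'
#' @param n Number of states (>= 1).
#' @param ruleset A [rule_set()].
#' @param seed RNG seed.
#' @param priors Optional named list mapping a variable to a probability
#'   vector over its value set.
#' @return List of `list(state, action, matched_ids)` records.
#' @export
generate_patient_states <- function(n, ruleset, seed = 1, priors = NULL) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(inherits(ruleset, "rule_set"))
  schema <- patient_state_schema()
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    vars <- lapply(names(schema), function(v) {
      p <- priors[[v]]
      sample(schema[[v]], 1, prob = p)
    })
    names(vars) <- names(schema)
    st <- patient_state(vars,
                        first_name = sprintf("Synth%04d", i),
                        last_name = "Patient",
                        height = stats::runif(1, 1.40, 1.95))
    res <- evaluate_rules(st, ruleset)
    list(state = st, action = res$action, matched_ids = res$matched_ids)
  })
}

# procedural identity texture: sum of two oriented sinusoidal gratings
.texture_image <- function(size, freq, theta, phase, contrast, noise_sd) {
  xs <- matrix(rep(seq_len(size), each = size), size)
  ys <- matrix(rep(seq_len(size), times = size), size)
  u <- cos(theta) * xs + sin(theta) * ys
  v <- -sin(theta) * xs + cos(theta) * ys
  img <- 128 + contrast * 60 * sin(2 * pi * freq * u + phase) +
    contrast * 40 * sin(2 * pi * freq * 1.7 * v + phase / 2)
  img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size)
  .clip255(img)
}

#' Generate labelled synthetic ward images
#'
#' Each identity (`First`, `Second`, `Third`) renders as a distinct
#' procedural grating texture (orientation/frequency signature) with
#' per-image random phase and noise; the `None` class draws a fresh
#' random texture per image from orientations between the identity
#' signatures, emulating unseen people. Labels follow the re-id classes.
#'
#' @param identities Number of patient identities (<= 3).
#' @param per_class Images per class (>= 2 so a split is possible).
#' @param size Image side in pixels.
#' @param noise_sd Pixel noise standard deviation.
#' @param seed RNG seed; output is a pure function of (params, seed).
#' @param out_dir Optional directory; when given, images are written as
#'   PNGs in one subfolder per label.
#' @return List of `list(image, label)` records.
#' @export
generate_ward_images <- function(identities = 3, per_class = 10, size = 48,
                                 noise_sd = 6, seed = 1, out_dir = NULL) {
  if (identities > 3) stop("at most 3 patient identities")
  if (per_class < 2) stop("per_class must be >= 2 (train/test split)")
  set.seed(seed)
  id_labels <- c("First", "Second", "Third")[seq_len(identities)]
  id_theta <- c(0, pi / 4, pi / 2)[seq_len(identities)]
  id_freq <- c(0.10, 0.13, 0.16)[seq_len(identities)]
  out <- list()
  for (i in seq_len(identities)) {
    for (j in seq_len(per_class)) {
      img <- .texture_image(size, id_freq[i], id_theta[i],
                            phase = stats::runif(1, 0, 2 * pi),
                            contrast = stats::runif(1, 0.9, 1.1),
                            noise_sd = noise_sd)
      out[[length(out) + 1L]] <- list(image = img, label = id_labels[i])
    }
  }
  for (j in seq_len(per_class)) {
    # unseen texture per image: a smoothed random field, nothing like the
    # patients' grating signatures (visitors, staff, other patients)
    raw <- matrix(stats::rnorm(size^2, 128, 90), size)
    img <- .clip255(denoise(raw, kernel_size = 1 + 2 * sample(1:3, 1)) +
                      matrix(stats::rnorm(size^2, 0, noise_sd), size))
    out[[length(out) + 1L]] <- list(image = img, label = "None")
  }
  if (!is.null(out_dir)) {
    for (lab in unique(vapply(out, `[[`, character(1), "label"))) {
      dir.create(file.path(out_dir, lab), recursive = TRUE,
                 showWarnings = FALSE)
    }
    counters <- list()
    for (rec in out) {
      counters[[rec$label]] <- (counters[[rec$label]] %||% 0) + 1
      write_image_png(rec$image,
                      file.path(out_dir, rec$label,
                                sprintf("img%03d.png", counters[[rec$label]])))
    }
  }
  out
}

#' Read a scenario script from YAML
#'
#' @param path YAML path with fields mirroring [scenario_script()]
#'   (`segments` as a list of `{start, end, pose, amplitude}` entries).
#' @return A [scenario_script()].
#' @export
read_scenario_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  segments <- do.call(rbind, lapply(doc$segments, function(s) {
    data.frame(start = s$start, end = s$end, pose = s$pose,
               amplitude = s$amplitude %||% 0.6)
  }))
  sleep_intervals <- if (!is.null(doc$sleep_intervals)) {
    do.call(rbind, lapply(doc$sleep_intervals, function(s) {
      data.frame(start = s$start, end = s$end)
    }))
  }
  scenario_script(segments,
                  subject = doc$subject %||% "patient1",
                  fps = doc$fps %||% 10,
                  baseline_hr = doc$baseline_hr %||% 70,
                  sleep_hr_drop = doc$sleep_hr_drop %||% 15,
                  sleep_intervals = sleep_intervals,
                  noise_sd = doc$noise_sd %||% 0,
                  occlusion_prob = doc$occlusion_prob %||% 0,
                  seed = doc$seed %||% 1)
}
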