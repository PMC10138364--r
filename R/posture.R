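#' @name posture
#' @title Static posture classification from skeleton geometry
#' @description
#' A single skeleton is reduced to a small set of translation- and
#' scale-invariant geometric features and classified into one of four
#' coarse static classes: `upright`, `sitting`, `fallen_on_ground`,
#' `lying_like` (or `unknown` when too few landmarks are detected).
#' The temporal module later splits `upright` into walking/standing and
#' `lying_like` into lying-in-bed/sleeping; that split is inherently
#' temporal and never attempted from a single frame.
NULL

# canonical-order landmark indices (see keypoint_names())
.KP <- list(head = 1:5, l_shoulder = 6L, r_shoulder = 7L, l_hip = 12L,
            r_hip = 13L, l_knee = 14L, r_knee = 15L, l_ankle = 16L,
            r_ankle = 17L, legs = 14:17)

.mid_point2 <- function(x, y, det, i_left, i_right) {
  use <- c(i_left, i_right)[det[c(i_left, i_right)]]
  if (length(use) == 0) return(c(NA_real_, NA_real_))
  c(mean(x[use]), mean(y[use]))
}

.angle_deg <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Extract geometric pose features from a skeleton
#'
#' Features: `torso_angle` (degrees of the mid-shoulder to mid-hip axis
#' from vertical), `bbox_aspect` (bbox height/width), `hip_knee_angle`
#' (knee flexion: angle at the knee between thigh and shank, averaged over
#' sides with all three landmarks detected), `leg_extent` (vertical leg
#' extension below the hips in torso lengths), `head_above_hips` (vertical
#' offset of the head above the hips, normalized by torso length),
#' `detected_fraction` and `torso_length` (pixels; the only
#' scale-dependent feature). Undetected landmarks are excluded from every
#' mean and angle. With fewer than 4 detected keypoints, or no detected
#' shoulder or hip, the features are flagged unreliable rather than
#' raising an error.
#'
#' @param skel A [skeleton()].
#' @param bed_region Optional `c(x_min, y_min, x_max, y_max)` bed polygon
#'   (axis-aligned); sets the `in_bed` feature from the skeleton's hip
#'   (or bbox) centre.
#' @return A list of class `pose_features`.
#' @export
extract_features <- function(skel, bed_region = NULL) {
  stopifnot(inherits(skel, "skeleton"))
  kx <- skel$keypoints$x
  ky <- skel$keypoints$y
  det <- skel$keypoints$confidence >= skel$detection_threshold
  n_det <- sum(det)
  shoulders <- .mid_point2(kx, ky, det, .KP$l_shoulder, .KP$r_shoulder)
  hips <- .mid_point2(kx, ky, det, .KP$l_hip, .KP$r_hip)
  reliable <- n_det >= 4 && !anyNA(shoulders) && !anyNA(hips)

  torso_vec <- hips - shoulders          # points from shoulders toward hips
  torso_length <- sqrt(sum(torso_vec^2))
  # angle from vertical; y grows downward so a standing torso vector is (0, +)
  torso_angle <- if (reliable && torso_length > 0) {
    .angle_deg(torso_vec, c(0, 1))
  } else NA_real_

  bbox <- skel$bbox
  bbox_aspect <- if (!anyNA(bbox) && (bbox[3] - bbox[1]) > 0) {
    (bbox[4] - bbox[2]) / (bbox[3] - bbox[1])
  } else NA_real_

  knee_angles <- c()
  for (side in list(c(.KP$l_hip, .KP$l_knee, .KP$l_ankle),
                    c(.KP$r_hip, .KP$r_knee, .KP$r_ankle))) {
    if (all(det[side])) {
      a <- .angle_deg(c(kx[side[1]] - kx[side[2]], ky[side[1]] - ky[side[2]]),
                      c(kx[side[3]] - kx[side[2]], ky[side[3]] - ky[side[2]]))
      if (!is.na(a)) knee_angles <- c(knee_angles, a)
    }
  }
  hip_knee_angle <- if (length(knee_angles)) mean(knee_angles) else NA_real_

  # vertical leg extension below the hips, torso-normalized: ~1.1 standing,
  # ~0.6 sitting, ~0 lying; robust to occlusion (any one leg landmark works)
  leg_idx <- .KP$legs[det[.KP$legs]]
  leg_extent <- NA_real_
  if (reliable && length(leg_idx) && torso_length > 0) {
    leg_extent <- (max(ky[leg_idx]) - hips[2]) / torso_length
  }

  head_idx <- .KP$head[det[.KP$head]]
  head_above_hips <- NA_real_
  if (reliable && length(head_idx) && torso_length > 0) {
    head_above_hips <- (hips[2] - mean(ky[head_idx])) / torso_length
  }

  in_bed <- NA
  centre <- if (!anyNA(hips)) hips else if (!anyNA(bbox)) {
    c((bbox[1] + bbox[3]) / 2, (bbox[2] + bbox[4]) / 2)
  } else c(NA_real_, NA_real_)
  if (!is.null(bed_region) && !anyNA(centre)) {
    in_bed <- centre[1] >= bed_region[1] && centre[1] <= bed_region[3] &&
      centre[2] >= bed_region[2] && centre[2] <= bed_region[4]
  }

  structure(list(torso_angle = torso_angle,
                 bbox_aspect = bbox_aspect,
                 hip_knee_angle = hip_knee_angle,
                 leg_extent = leg_extent,
                 head_above_hips = head_above_hips,
                 detected_fraction = n_det / 17,
                 torso_length = torso_length,
                 in_bed = in_bed,
                 reliable = reliable),
            class = "pose_features")
}

# transparent rule-based fallback classifier over the geometric features;
# thresholds chosen from the stick-model geometry (standing knee ~ 175 deg,
# sitting knee ~ 90 deg; torso within 45 deg of vertical counts as upright)
.classify_static_rules <- function(f) {
  if (!isTRUE(f$reliable) || is.na(f$torso_angle)) {
    return(list(value = "unknown", confidence = 0))
  }
  if (f$torso_angle >= 45) {
    value <- if (isTRUE(f$in_bed)) "lying_like" else "fallen_on_ground"
    conf <- min(1, f$torso_angle / 90)
    return(list(value = value, confidence = conf))
  }
  sitting <- if (!is.na(f$hip_knee_angle)) {
    f$hip_knee_angle < 135
  } else if (!is.na(f$leg_extent)) {
    f$leg_extent < 0.85          # folded legs when the knee angle is occluded
  } else {
    FALSE
  }
  if (sitting) {
    return(list(value = "sitting", confidence = 0.8))
  }
  list(value = "upright", confidence = min(1, (45 - f$torso_angle) / 45))
}

# model frame for the tree learner; occluded secondary features are
# imputed with their neutral standing values so routing stays defined
.features_to_frame <- function(features_list) {
  num <- function(field, default = NA_real_) {
    v <- vapply(features_list, function(f) f[[field]] %||% NA_real_, numeric(1))
    if (!is.na(default)) v[is.na(v)] <- default
    v
  }
  data.frame(
    torso_angle = num("torso_angle"),
    bbox_aspect = num("bbox_aspect", 5),
    hip_knee_angle = num("hip_knee_angle", 180),
    leg_extent = num("leg_extent", 1.1),
    head_above_hips = num("head_above_hips", 1.25),
    detected_fraction = num("detected_fraction"),
    in_bed = vapply(features_list, function(f) as.numeric(isTRUE(f$in_bed)), numeric(1)))
}

#' Classify a static pose
#'
#' With a trained [train_pose_model()] model the features are routed
#' through its decision tree; with `model = NULL` a transparent rule-based
#' fallback over the same features is used. Unreliable features always
#' yield `unknown`. Ties favour the more dangerous class (fallen >
#' lying-like > sitting > upright).
#'
#' @param features A `pose_features` object from [extract_features()].
#' @param model A `pose_model`, or `NULL` for the rule-based fallback.
#' @return List of class `static_pose` with `value` and `confidence`.
#' @export
classify_static <- function(features, model = NULL) {
  stopifnot(inherits(features, "pose_features"))
  if (is.null(model)) {
    out <- .classify_static_rules(features)
  } else {
    if (!inherits(model, "pose_model")) {
      stop("model must be a pose_model (or NULL for the rule-based fallback)")
    }
    if (!isTRUE(features$reliable) || is.na(features$torso_angle)) {
      out <- list(value = "unknown", confidence = 0)
    } else {
      df <- .features_to_frame(list(features))
      route <- .tree_route(model$root, df[1, , drop = FALSE])
      counts <- unlist(route$counts)
      out <- list(value = route$action,
                  confidence = max(counts) / sum(counts))
    }
  }
  structure(out, class = "static_pose")
}

#' @export
print.static_pose <- function(x, ...) {
  cat(sprintf("<static_pose> %s (confidence %.2f)\n", x$value, x$confidence))
  invisible(x)
}

#' Train the posture model
#'
#' Fits the same Gini decision-tree learner used for care-plan decision
#' support to labelled geometric features. Deterministic given the data
#' order; serializable to JSON with [write_tree_json()].
#'
#' @param labelled List of `list(features, pose)` pairs, `pose` one of the
#'   four static classes.
#' @param max_depth,min_samples Pre-pruning hyperparameters.
#' @param seed Accepted for interface uniformity; the learner is
#'   deterministic.
#' @return An object of class `pose_model`.
#' @export
train_pose_model <- function(labelled, max_depth = 4, min_samples = 5,
                             seed = NULL) {
  if (length(labelled) < 10) stop("need at least 10 labelled examples")
  y <- vapply(labelled, function(l) as.character(l$pose), character(1))
  if (length(unique(y)) < 2) {
    stop("training error: need at least 2 classes, got only '", unique(y), "'")
  }
  x <- .features_to_frame(lapply(labelled, `[[`, "features"))
  keep <- !is.na(x$torso_angle)
  tree <- fit_decision_tree(x[keep, , drop = FALSE], y[keep],
                            max_depth = max_depth, min_samples = min_samples,
                            class_priority = static_pose_severity())
  tree$feature_names <- names(x)
  class(tree) <- c("pose_model", "gini_tree")
  tree
}

#' Load a posture model from JSON
#'
#' @param path JSON path written by [write_tree_json()].
#' @return A `pose_model`.
#' @export
read_pose_model <- function(path) {
  read_tree_json(path, class = c("pose_model", "gini_tree"))
}
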