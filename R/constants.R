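#' Canonical keypoint names
#'
#' The 17 anatomical landmarks of a COCO-style 2D skeleton, in canonical
#' order: nose, eyes, ears, shoulders, elbows, wrists, hips, knees, ankles
#' (left before right within each pair).
#'
#' @return Character vector of length 17.
#' @export
keypoint_names <- function() {
  c("nose",
    "left_eye", "right_eye",
    "left_ear", "right_ear",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle")
}

#' Final pose labels
#'
#' The six per-minute pose classes emitted by the monitoring protocol.
#'
#' @return Character vector of length 6.
#' @export
pose_labels <- function() {
  c("walking", "standing", "sitting",
    "fallen_on_ground", "lying_in_bed", "sleeping")
}

# internal single-frame classes; upright is split into walking/standing and
# lying_like into lying_in_bed/sleeping by the temporal module
static_pose_values <- function() {
  c("upright", "sitting", "fallen_on_ground", "lying_like", "unknown")
}

# severity order used for tie-breaking: dangerous states never lose a tie
static_pose_severity <- function() {
  c(fallen_on_ground = 4L, lying_like = 3L, sitting = 2L, upright = 1L,
    unknown = 0L)
}

#' Care-plan actions
#'
#' The four possible care-plan outputs; `continue_current_treatment` is the
#' default when no rule matches.
#'
#' @return Character vector of length 4.
#' @export
plan_actions <- function() {
  c("continue_current_treatment", "monitor", "adjust", "extra_situation")
}

# higher = more severe; drives rule evaluation order and leaf tie-breaks
plan_action_severity <- function() {
  c(continue_current_treatment = 1L, monitor = 2L, adjust = 3L,
    extra_situation = 4L)
}

lighting_tags <- function() c("well_lit", "semi_lit", "poorly_lit")

# default confidence below which a keypoint counts as undetected
DEFAULT_DETECTION_THRESHOLD <- 0.05

`%||%` <- function(a, b) if (is.null(a)) b else a
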