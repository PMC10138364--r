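---
title: "Methods: posture monitoring, habit tracking and care-plan decision support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posture monitoring, habit tracking and care-plan decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gericare` implements the computational core of a camera-plus-wearable
monitoring workflow for geriatric wards: posture recognition over 2D
skeleton keypoints with a timed verification protocol, fusion with
wristband vitals, multi-day movement-habit change detection, a
rule-plus-decision-tree care-plan recommender over a 21-variable patient
state, bag-of-visual-words patient re-identification, and a multiclass
evaluation suite. This vignette explains the models, the tunable
parameters, the synthetic data the package ships in place of (private)
ward recordings, and the design decisions taken where the protocol left
choices open.

## The vision input and its geometry

The vision input is a stream of per-frame skeletons: 17 anatomical
landmarks per person (nose, eyes, ears, shoulders, elbows, wrists, hips,
knees, ankles), each with pixel coordinates and a confidence value. Pose
*estimation* (running a detector plus keypoint network over video) is out
of scope: detectors are trained networks, and the package consumes their
output through `read_skeleton_stream()`. Coordinates are image pixels
with the origin at the top-left, x rightward, y downward, 0-based; a
keypoint with confidence below the detection threshold (default 0.05, a
common convention for keypoint estimators) is treated as undetected and
excluded from every geometric computation.

Static posture classification reduces a skeleton to translation- and
scale-invariant features:

* `torso_angle` — degrees from vertical of the mid-shoulder to mid-hip
  axis (0 standing, 90 lying);
* `hip_knee_angle` — knee flexion, the angle at the knee between thigh
  and shank, averaged over sides with all three landmarks detected
  (about 180 standing, about 90 sitting);
* `leg_extent` — vertical leg extension below the hips in torso lengths
  (about 1.1 standing, 0.6 sitting, near 0 lying). This is the
  occlusion-robust backup for the knee angle: it needs only one detected
  knee or ankle, whereas the knee angle needs a full hip–knee–ankle
  chain on one side;
* `bbox_aspect`, `head_above_hips`, `detected_fraction`, and
  `torso_length` (the only scale-dependent feature, used for
  normalization elsewhere).

The static classes are deliberately coarse: `upright`, `sitting`,
`lying_like`, `fallen_on_ground`, `unknown`. Walking versus standing and
lying versus sleeping cannot be decided from one frame; those splits are
temporal and happen in the monitoring protocol. The published workflow
trains a posture classifier on thousands of manually labelled images but
does not state its features or mechanism; we chose geometric skeleton
features plus the same Gini decision-tree learner used for care-plan
support, with a transparent rule fallback, because the result is
auditable and needs no trained weights. Lying versus fallen at the
static level is a spatial prior: a horizontal skeleton inside a
configurable bed rectangle is `lying_like`, outside it
`fallen_on_ground`. Ties in class scores resolve by a fixed severity
order (fallen > lying > sitting > upright) so dangerous states are never
lost to a tie.

## The timed verification protocol

Video is analysed at one assessment per 5 seconds under the assumption
that no significant motion change happens faster; at 10 FPS that means
600 frames inspected and 12 assessments kept per minute. A pose is
verified over a window of three assessments spanning 15 s:

* any 2-of-3 `fallen_on_ground` verdicts confirm a fall immediately
  (severity bias — a fall must not wait for unanimity);
* otherwise a 2-of-3 majority is required, else the minute is
  `undetermined`. Strict unanimity would starve labels under keypoint
  noise, which is why 2-of-3 was chosen;
* an `upright` majority is split by the motion score — the mean keypoint
  displacement between adjacent assessments normalized by torso length —
  at a threshold of 0.05 (unitless): above is `walking`, below
  `standing`;
* a `lying_like` majority extends the assessment to a full minute and is
  resolved with the wristband: `sleeping` iff the band reports sleep
  state for the majority of the minute, or the subject is essentially
  still (motion below 0.02) with mean heart rate at least 10 bpm below
  the personal awake baseline; otherwise `lying_in_bed`. The protocol
  states that lying/sleeping correlate with bracelet sleep time and
  heart rate but gives no thresholds; 0.05/0.02/10 bpm are defaults
  chosen on the synthetic suite and exposed in `monitor_config()`.

The awake heart-rate baseline is the trailing 7-day median of heart-rate
samples taken while the band does not report sleep — the workflow implies
personal baselines ("his heart rate was reduced") without defining one.
Missing vitals are carried forward (LOCF) with a staleness bound of 24 h;
the published system carries the last recorded value forward but states
no bound, and an unbounded carry would silently trust week-old vitals.
`locf_fill()` records which entries were true observations, so carried
values never age-reset the staleness clock and the fill is idempotent.

Minutes with an `undetermined` verification inherit the previous verified
pose for at most 5 minutes (consistent with the system's stated
resistance to data deficiencies); a subject absent for a full minute is a
gap, not an error. Labelled minutes accumulate into a per-day activity
ledger (hours per pose, at most 24 per day), and each transition into
`fallen_on_ground` emits one alert event.

## Movement-habit change

Active hours are `ActH = walking + sitting + standing` per day. With a
threshold `kth = 12.5%`, the day-over-day percentage differences
`Diff(a, b) = ((a − b)/b)·100` over the last three days decide the
verdict: both diffs at or below `−kth` means `slowed_down`, both at or
above `+kth` means `increased`, anything else `unchanged`. The printed
formula divides by `b` unguarded; we return `+Inf` for `b = 0, a > 0`
(preserving the monotone comparison semantics) and 0 for `a = b = 0`.
The three-day lookback is fixed, matching the pseudocode; the
accompanying prose allows 1–3 days of lookback, which we note but do not
implement. Verdicts are scale-invariant in the hour values because the
diffs are ratios. A missing day yields `unchanged` flagged
`insufficient_data` rather than a guess.

## Care-plan decision support

A patient state holds 21 categorical variables (movement capability,
risk of collapse, bedsores, diseases, medication, BMI change, movement
habits, eating habits and capabilities, bowel habits, sleep, breathing,
pulse, blood pressure, temperature, saturation, urine output, fluid
intake, glycaemia, consciousness, pain) plus demographics. The published
variable table leaves several value sets open-ended ("etc."); the
package closes them with representative clinical values so that states
can be validated and sampled — the schema is in
`patient_state_schema()` and is the single source of truth for
validation, rule checking and tree splits.

Two interchangeable recommenders map a state to one of four actions
(`continue_current_treatment` — the default, `monitor`, `adjust`,
`extra_situation`):

* an IF-THEN **rule engine**. Rules are conjunctions of
  (variable, operator, value) conditions with an action and a priority.
  The production rule base of a real deployment (61 staff-authored
  rules) is private; the package ships an illustrative 18-rule set in
  the same form. Rule conflicts resolve severity-first (then priority,
  then id): the published workflow states no conflict policy, and
  severity-first guarantees an emergency is never masked by a blander
  rule that happens to match first. Validation happens at load time —
  a rule referencing an unknown variable or value never reaches
  evaluation;
* a **Gini decision tree** trained to emulate the rules. Splits
  greedily maximize the decrease of Gini impurity `1 − Σ p_j²`, with
  pre-pruning against overfitting: depth at most 3 and at least 6
  training records per leaf ("minimum number of samples in a node" is
  read as minimum samples per leaf, the standard pre-pruning
  semantics). Categorical variables split as one-hot equality tests
  rather than subset search — deterministic and interpretable at depth
  3. Leaf ties break toward the more severe action.

The published fit quality ("average classification error of 92%", which
its context suggests is accuracy misworded) was measured on private
data and cannot be reproduced; the package instead requires the tree,
trained on 5,000 rule-labelled synthetic states, to agree with the rule
engine on at least 85% of held-out states. Under uniform sampling the
bundled rule set yields roughly 53% extra-situation, 31% continue, 12%
adjust and 3% monitor labels, and a depth-3 tree captures the three
dominant single-condition rules (unconsciousness, falling, unbearable
pain) plus the default mass — measured agreement is 89–91% across seeds.
`recommend()` reports the matched rule ids or the root-to-leaf test path
alongside the action, and can populate the movement-habit variable from
the habit verdict first.

## Re-identification

Identity is assigned per image with a bag of visual words: local
descriptors, a K-means vocabulary, word-frequency histograms, and
one-vs-rest maximum-margin linear classifiers over at most four classes
— three ward patients plus an open-set `None` class for staff, visitors
and anyone else. The published description names SIFT only as an
example; the package uses a deterministic dense-grid descriptor
(magnitude-weighted gradient-orientation histograms over a 2×2 cell grid
per 8×8 patch, L2-normalized, flat patches dropped), which keeps the
pipeline free of randomness in detection. The vocabulary defaults to 64
words (no size is published); Lloyd's iterations are seeded and the
within-cluster objective is non-increasing. Encoding assigns each
descriptor to its nearest centroid (ties to the lowest index) and
L1-normalizes the counts; an image with no descriptors yields an
all-zero sentinel histogram. The per-class hyperplanes are stored
explicitly as weight vectors, so models serialize to JSON and
predictions are exactly reproducible. A prediction whose top margin
falls below a threshold (default 0) is rejected to `None` — the
published open-set setting names no mechanism, and margin rejection is
the minimal one.

## Evaluation

The metric suite matches the published evaluation exactly: a confusion
matrix with actual classes as rows and predictions as columns; per-class
one-vs-rest precision, recall and F1 (`2PR/(P+R)`, zeros with a flag for
empty denominators); the macro F1 (unweighted mean); the weighted F1
`Σ (k_i/N)·F1_i`; and per-class one-vs-rest ROC AUC computed as the
midrank Mann–Whitney statistic (equivalent to trapezoidal integration
with tie midranking). The printed weighted-F1 formula carries an extra
division by the number of classes that would make its own reported value
impossible (the weights already sum to one); we implement the weighted
sum, which is consistent with the published numbers, and flag the
formula as a presumed typo. For comparisons against 4-decimal published
tables, metrics are computed at full precision and rounded half-up only
at report time (`round_half_up()`), since banker's rounding would differ
on exact .5 boundaries.

## Synthetic data: what it emulates and what it does not

No recordings or patient data are published (privacy restrictions), so
the package generates every input it needs, deterministically from a
script and a seed:

* **Skeleton streams** use a 6-segment stick model with plausible
  stature scaled to pixels: standing is a vertical figure; walking adds
  horizontal translation (default 0.6 torso lengths per second) and limb
  oscillation; sitting flexes the knees to about 90°; lying and sleeping
  are horizontal figures inside the bed rectangle (sleeping with
  near-zero motion, lying with optional restless sway); a fall is a
  horizontal figure on the floor. Noise is isotropic Gaussian on
  keypoints (scripted as a fraction of torso length) and occlusion is
  per-keypoint dropout — mirroring the real failure mode of blankets
  covering sleepers. The moderate-noise benchmark uses σ = 2% of torso
  length with 15% dropout.
* **Vitals** are baseline heart rate plus a small circadian sine and
  Gaussian noise, a scripted drop (default 15 bpm) with `sleep_state`
  set inside sleep intervals, and scripted dropouts for LOCF testing.
* **Patient states** sample each variable independently (uniformly by
  default) and are labelled by the rule engine, which is the ground
  truth for tree training.
* **Ward images** render each identity as a distinct procedural grating
  texture (orientation/frequency signature) with per-image phase and
  noise; the `None` class draws a fresh smoothed-noise texture per
  image, emulating ever-different outsiders.

What passing these benchmarks shows is that the *protocol logic* —
verification, fusion, ledgers, rules, trees, vocabularies, metrics — is
implemented correctly and behaves as designed under controlled noise. It
does not show that the accuracy figures transfer to real ward footage:
the stick model has none of the articulation variety, perspective,
multi-person occlusion or detector failure modes of real video, the
grating textures are far easier to separate than real appearances, and
the published accuracy numbers (91.63% posture accuracy, 87–91%
re-identification, AUC 0.879–0.943, 182 ms latency) come from private
data and hardware and are not reproduction targets.

## Numerical choices and degenerate inputs

Problem sizes used by the test suite and the acceptance script were
chosen to exercise every code path at desk scale: 150 s per pose at
1 FPS for the posture benchmarks, 5,000/1,000 train/held-out states for
the tree, 20 images per class (14 train / 6 test) for re-identification,
day-long monitoring scripts at one frame per sampling period (the
sampler keeps one frame per 5 s tick regardless, so a higher FPS only
adds frames it would discard). Degenerate inputs prefer flags over
exceptions where the protocol must keep running: unreliable features
give `unknown`, undefined motion scores carry an `undefined` attribute,
a windowless minute is a gap, an all-missing vitals window decides from
motion alone and is flagged low-confidence. Hard validation errors are
reserved for malformed files, schema violations and invalid parameters,
and name the offending landmark, variable or field.

Image conditioning (`brighten`, `crop_image`, `denoise`, `edge_detect`)
implements the four published preprocessing steps with the simplest
member of each named family — gamma mapping, rectangular crop, box
low-pass, Sobel gradient — since no operators or parameters are
published; all are parameterized, clip to [0, 255], and use symmetric
border reflection wherever a neighbourhood is needed.

## Known limitations

* Single camera, single room: no cross-camera tracking or multi-view
  fusion; identity within a stream is taken from the skeleton's person
  tag.
* The 15-s verification window interacts with subject absence by simple
  gap rules (a choice; the published protocol does not specify it).
* The bundled rule set is illustrative, not clinical guidance.
* The tree learner's one-hot splits cannot express subset conditions in
  one node; rules of the form "value ∈ {a, b}" cost two levels.
* `weighted_f1` needs per-class counts, which published tables do not
  always print; it is therefore exercised on synthetic benchmarks only.
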