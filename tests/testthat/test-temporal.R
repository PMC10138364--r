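test_that("the sampler keeps one assessment per period", {
  sc <- scenario_script(data.frame(start = 0, end = 60, pose = "standing",
                                   amplitude = 0), fps = 10, seed = 1)
  stream <- generate_skeleton_sequence(sc)
  expect_length(stream, 600)
  expect_length(sample_assessments(stream, period = 5), 12)
  expect_length(sample_assessments(stream, period = 60), 1)
  expect_length(sample_assessments(frame_stream(), period = 5), 0)
})

test_that("sampling under timestamp jitter matches a brute-force scheduler", {
  set.seed(21)
  for (rep in 1:4) {
    ts <- sort(runif(200, 0, 90))
    frames <- lapply(ts, function(t) {
      frame_record(t, list(make_skeleton(standing_coords(), t = t)))
    })
    stream <- frame_stream(frames)
    period <- sample(c(3, 5, 7), 1)
    got <- sample_assessments(stream, period = period)
    # independent scan: ticks from the first frame, nearest frame within
    # half a period
    count <- 0
    tick <- min(ts)
    while (tick <= max(ts) + 1e-9) {
      if (min(abs(ts - tick)) <= period / 2) count <- count + 1
      tick <- tick + period
    }
    expect_length(got, count)
    # dense streams: count equals floor(duration/period) + 1 ticks
    expect_equal(count, floor((max(ts) - min(ts)) / period) + 1)
  }
})

test_that("motion score is a normalized symmetric displacement", {
  a <- make_skeleton(standing_coords())
  expect_equal(motion_score(a, a), 0)
  # translation by exactly one torso length -> 1.0
  b <- make_skeleton(sweep(standing_coords(), 2, c(80, 0), `+`))
  expect_equal(motion_score(a, b), 1.0)
  # random pair vs naive per-keypoint computation
  set.seed(22)
  c2 <- make_skeleton(standing_coords() + matrix(rnorm(34, 0, 10), 17, 2))
  d <- sqrt((a$keypoints$x - c2$keypoints$x)^2 +
              (a$keypoints$y - c2$keypoints$y)^2)
  tl <- function(s) {
    sh <- c(mean(s$keypoints$x[6:7]), mean(s$keypoints$y[6:7]))
    hp <- c(mean(s$keypoints$x[12:13]), mean(s$keypoints$y[12:13]))
    sqrt(sum((sh - hp)^2))
  }
  expect_equal(motion_score(a, c2), mean(d) / mean(c(tl(a), tl(c2))),
               tolerance = 1e-9)
  expect_equal(motion_score(a, c2), motion_score(c2, a))
  # fewer than 3 common detected keypoints -> undefined flag
  conf <- rep(0, 17); conf[1:2] <- 0.9
  sparse <- make_skeleton(standing_coords(), conf = conf)
  expect_true(is.na(motion_score(a, sparse)))
  expect_true(attr(motion_score(a, sparse), "undefined"))
})

test_that("verify_pose matches the hand-enumerated truth table", {
  still <- make_skeleton(standing_coords())
  mk_window <- function(classes) {
    poses <- lapply(classes, function(v) {
      structure(list(value = v, confidence = 1), class = "static_pose")
    })
    assessments <- lapply(0:2, function(i) {
      list(timestamp = i * 5, subject = "p1", skeleton = still)
    })
    assessment_window(assessments, poses)
  }
  vals <- c("upright", "sitting", "lying_like", "fallen_on_ground")
  grid <- expand.grid(a = vals, b = vals, c = vals,
                      stringsAsFactors = FALSE)
  # independent statement of the protocol: 2-of-3 fallen wins outright;
  # else a >= 2/3 majority is required; upright resolves by motion (zero
  # here, hence standing); lying stays deferred as lying_like
  oracle <- function(cls) {
    if (sum(cls == "fallen_on_ground") >= 2) return("fallen_on_ground")
    tab <- table(cls)
    if (max(tab) < 2) return("undetermined")
    major <- names(tab)[which.max(tab)]
    switch(major, upright = "standing", major)
  }
  for (i in seq_len(nrow(grid))) {
    cls <- unlist(grid[i, ])
    expect_equal(verify_pose(mk_window(cls)), oracle(cls),
                 info = paste(cls, collapse = "/"))
  }
})

test_that("a translating upright subject verifies as walking", {
  assessments <- lapply(0:2, function(i) {
    list(timestamp = i * 5, subject = "p1",
         skeleton = make_skeleton(
           sweep(standing_coords(), 2, c(i * 120, 0), `+`), t = i * 5))
  })
  w <- assessment_window(assessments)
  expect_equal(verify_pose(w), "walking")
  # identical standing skeletons -> standing
  w0 <- assessment_window(lapply(0:2, function(i) {
    list(timestamp = i * 5, subject = "p1",
         skeleton = make_skeleton(standing_coords(), t = i * 5))
  }))
  expect_equal(verify_pose(w0), "standing")
  # verify_pose never emits sleeping
  expect_false(verify_pose(w0) == "sleeping")
})

test_that("lying/sleeping fusion follows the written rule on a grid", {
  lying <- standing_coords(80, c(0, 0))
  lying <- cbind(lying[, 2], -lying[, 1] * 0.4)
  still_sk <- function(t, jiggle = 0) {
    make_skeleton(sweep(lying, 2, c(500 + jiggle, 300), `+`), t = t)
  }
  mk_assessments <- function(moving) {
    lapply(0:12, function(i) {
      list(timestamp = i * 5, subject = "p1",
           skeleton = still_sk(i * 5, jiggle = if (moving) i * 8 else 0))
    })
  }
  mk_vitals <- function(sleep_state, hr) {
    vitals_series(data.frame(timestamp = seq(0, 60, 15),
                             heart_rate = hr, sleep_state = sleep_state))
  }
  baseline <- 70
  for (sleep_state in c(TRUE, FALSE)) {
    for (hr_off in c(-15, 0)) {
      for (moving in c(FALSE, TRUE)) {
        got <- disambiguate_lying(mk_assessments(moving),
                                  mk_vitals(sleep_state, baseline + hr_off),
                                  baseline_hr = baseline)
        want <- if (sleep_state || (!moving && hr_off <= -10)) {
          "sleeping"
        } else {
          "lying_in_bed"
        }
        expect_equal(as.character(got), want,
                     info = sprintf("sleep=%s hr_off=%d moving=%s",
                                    sleep_state, hr_off, moving))
      }
    }
  }
  # entirely missing vitals: motion decides, flagged low-confidence
  empty <- vitals_series(data.frame(timestamp = numeric(0)))
  got <- disambiguate_lying(mk_assessments(FALSE), empty, baseline_hr = 70)
  expect_equal(as.character(got), "sleeping")
  expect_true(attr(got, "low_confidence"))
  got2 <- disambiguate_lying(mk_assessments(TRUE), empty, baseline_hr = 70)
  expect_equal(as.character(got2), "lying_in_bed")
})

test_that("monitor reproduces a scripted day in the ledger to the minute", {
  # 1 h walking + 2 h sitting + 3 h lying (scaled-down day)
  seg <- data.frame(start = c(0, 3600, 10800),
                    end = c(3600, 10800, 21600),
                    pose = c("walking", "sitting", "lying_in_bed"),
                    amplitude = c(0.6, 0, 0.05))
  sc <- scenario_script(seg, fps = 0.2, seed = 30)
  stream <- generate_skeleton_sequence(sc)
  res <- monitor(stream, NULL,
                 config = monitor_config(bed_region = sc$bed_region))
  led <- res$ledger
  expect_equal(nrow(led), 1)
  expect_equal(led$walking, 1, tolerance = 0.02)
  expect_equal(led$sitting, 2, tolerance = 0.02)
  expect_equal(led$lying_in_bed, 3, tolerance = 0.02)
  # conservation: ledger hours equal labelled minutes / 60, never > 24
  total <- sum(led[, pose_labels()])
  expect_equal(total, nrow(res$labels) / 60)
  expect_lte(total, 24)
})

test_that("one scripted fall raises exactly one alert at the right minute", {
  seg <- data.frame(start = c(0, 600, 900),
                    end = c(600, 900, 1800),
                    pose = c("standing", "fallen_on_ground", "standing"),
                    amplitude = 0)
  sc <- scenario_script(seg, fps = 0.2, seed = 31)
  res <- monitor(generate_skeleton_sequence(sc), NULL,
                 config = monitor_config(bed_region = sc$bed_region))
  expect_equal(nrow(res$alerts), 1)
  expect_equal(res$alerts$minute, 600)
})

test_that("undetermined minutes inherit the previous pose up to the cap", {
  # subject visible 10 min, absent 20 min, visible again
  seg <- data.frame(start = c(0, 1800), end = c(600, 2400),
                    pose = "standing", amplitude = 0)
  sc <- scenario_script(seg, fps = 0.2, seed = 32)
  res <- monitor(generate_skeleton_sequence(sc), NULL,
                 config = monitor_config(bed_region = sc$bed_region,
                                         max_inherit_minutes = 5))
  gap_minutes <- res$labels$minute[res$labels$minute >= 600 &
                                     res$labels$minute < 1800]
  expect_length(gap_minutes, 5)  # inherited, then a real gap
  expect_true(all(res$labels$pose[res$labels$minute %in% gap_minutes] ==
                    "standing"))
})
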