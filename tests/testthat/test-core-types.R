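test_that("skeleton construction enforces the 17-landmark contract", {
  sk <- make_skeleton(standing_coords())
  expect_s3_class(sk, "skeleton")
  expect_equal(nrow(sk$keypoints), 17)
  expect_error(skeleton(sk$keypoints[1:16, ], 0), "17 keypoints")
  kp <- sk$keypoints
  kp$confidence[1] <- 1.5
  expect_error(skeleton(kp, 0), "\\[0, 1\\]")
  # bbox contains every detected keypoint
  det <- detected_keypoints(sk)
  expect_true(all(sk$keypoints$x[det] >= sk$bbox[1] &
                    sk$keypoints$x[det] <= sk$bbox[3]))
  expect_true(all(sk$keypoints$y[det] >= sk$bbox[2] &
                    sk$keypoints$y[det] <= sk$bbox[4]))
})

test_that("skeleton streams survive a write/read round trip in both formats", {
  for (seed in c(1, 7)) {
    stream <- random_stream(6, seed = seed)
    for (fmt in c("keypoint_json", "csv")) {
      path <- tempfile(fileext = if (fmt == "csv") ".csv" else ".json")
      write_skeleton_stream(stream, path, format = fmt)
      back <- read_skeleton_stream(path, format = fmt)
      expect_stream_equal(stream, back)
      unlink(path)
    }
  }
})

test_that("empty streams round-trip and malformed input is reported", {
  path <- tempfile(fileext = ".json")
  write_skeleton_stream(frame_stream(), path)
  expect_length(read_skeleton_stream(path), 0)
  unlink(path)

  # dropping a keypoint column names the landmark
  stream <- random_stream(2, seed = 3)
  csv <- tempfile(fileext = ".csv")
  write_skeleton_stream(stream, csv, format = "csv")
  df <- read.csv(csv)
  df$kp_left_knee_x <- NULL
  write.csv(df, csv, row.names = FALSE, na = "")
  expect_error(read_skeleton_stream(csv, format = "csv"), "left_knee")
  unlink(csv)
})

test_that("strict reading rejects non-monotone timestamps", {
  stream <- random_stream(3, seed = 2)
  csv <- tempfile(fileext = ".csv")
  write_skeleton_stream(stream, csv, format = "csv")
  df <- read.csv(csv)
  df$timestamp <- rev(df$timestamp)
  write.csv(df, csv, row.names = FALSE, na = "")
  expect_error(read_skeleton_stream(csv, format = "csv", strict = TRUE),
               "ordering")
  unlink(csv)
})

test_that("vitals CSV round-trips with empty cells as missing", {
  v <- vitals_series(data.frame(
    timestamp = c(0, 60, 120), heart_rate = c(72, NA, 75),
    spo2 = c(97, 96, NA), sleep_state = c(FALSE, NA, TRUE),
    source = "band"))
  path <- tempfile(fileext = ".csv")
  write_vitals_csv(v, path)
  expect_equal(readLines(path, n = 1),
               paste0("\"timestamp\",\"heart_rate\",\"spo2\",\"systolic\",",
                      "\"diastolic\",\"weight\",\"sleep_state\",",
                      "\"sleep_hours\",\"source\""))
  back <- read_vitals_csv(path)
  expect_equal(back$heart_rate, v$heart_rate)
  expect_equal(back$sleep_state, v$sleep_state)
  unlink(path)
  expect_error(vitals_series(data.frame(timestamp = 0, heart_rate = -5)),
               "non-positive")
  expect_error(vitals_series(data.frame(timestamp = 0, sleep_hours = 25)),
               "sleep_hours")
})

test_that("locf_fill carries values forward within the staleness bound", {
  v <- vitals_series(data.frame(timestamp = c(0, 60, 120),
                                heart_rate = c(72, NA, NA)))
  filled <- locf_fill(v, "heart_rate", max_staleness = 300)
  expect_equal(filled$heart_rate, c(72, 72, 72))

  # series with no missing values is a fixed point on the data
  full <- vitals_series(data.frame(timestamp = 0:3 * 60,
                                   heart_rate = c(70, 71, 72, 73)))
  expect_equal(locf_fill(full, "heart_rate")$heart_rate, full$heart_rate)

  expect_error(locf_fill(v, "pulse_ox"), "unknown vitals field")
})

test_that("gaps longer than max_staleness stay missing (enumerated)", {
  # one observation at t=0 then a run of gaps at 60 s spacing; the rule
  # says a gap fills iff its age <= max_staleness
  for (max_stale in c(0, 59, 60, 150, 299, 300)) {
    v <- vitals_series(data.frame(timestamp = 0:6 * 60,
                                  heart_rate = c(80, rep(NA, 6))))
    filled <- locf_fill(v, "heart_rate", max_staleness = max_stale)
    expected <- c(80, ifelse(1:6 * 60 <= max_stale, 80, NA))
    expect_equal(filled$heart_rate, expected,
                 info = paste("max_staleness =", max_stale))
  }
})

test_that("locf_fill is idempotent and never alters observed values", {
  set.seed(42)
  for (rep in 1:5) {
    hr <- round(runif(20, 55, 100))
    hr[sample(20, 8)] <- NA
    v <- vitals_series(data.frame(timestamp = 0:19 * 45, heart_rate = hr))
    once <- locf_fill(v, "heart_rate", max_staleness = 120)
    twice <- locf_fill(once, "heart_rate", max_staleness = 120)
    expect_equal(once, twice)
    obs <- !is.na(hr)
    expect_equal(once$heart_rate[obs], hr[obs])
  }
})

test_that("patient states validate against the schema, listing offenders", {
  st <- base_state()
  expect_true(validate_patient_state(st))
  expect_error(base_state(RiskC = "extreme"), "RiskC")
  err <- tryCatch(patient_state(modifyList(unclass(base_state()),
                                           list(Pain = "awful", height = 2.5))),
                  error = conditionMessage)
  expect_match(err, "Pain")
  expect_match(err, "height")
})

test_that("patient states round-trip through JSON", {
  states <- list(base_state(), base_state(Pain = "severe", RiskC = "high"))
  path <- tempfile(fileext = ".json")
  write_patient_states(states, path)
  back <- read_patient_states(path)
  expect_equal(back[[2]][["Pain"]], "severe")
  expect_equal(back[[1]][["MoveH"]], "unchanged")
  unlink(path)
})
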