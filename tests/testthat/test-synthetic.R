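test_that("generators are pure functions of script and seed", {
  seg <- data.frame(start = 0, end = 30, pose = "walking", amplitude = 0.6)
  sc <- scenario_script(seg, fps = 5, noise_sd = 0.02,
                        occlusion_prob = 0.1, seed = 7)
  s1 <- generate_skeleton_sequence(sc)
  s2 <- generate_skeleton_sequence(sc)
  expect_equal(s1, s2)
  v1 <- generate_vitals(sc, sample_interval = 10, dropout_prob = 0.2)
  v2 <- generate_vitals(sc, sample_interval = 10, dropout_prob = 0.2)
  expect_equal(v1, v2)
  rs <- load_ruleset(demo_ruleset_path())
  expect_equal(generate_patient_states(20, rs, seed = 5),
               generate_patient_states(20, rs, seed = 5))
  expect_equal(generate_ward_images(per_class = 3, seed = 5),
               generate_ward_images(per_class = 3, seed = 5))
})

test_that("a 60 s script at 10 fps produces 600 frames", {
  sc <- scenario_script(data.frame(start = 0, end = 60, pose = "standing",
                                   amplitude = 0), fps = 10, seed = 1)
  expect_length(generate_skeleton_sequence(sc), 600)
})

test_that("zero-noise standing frames have exactly vertical torsos", {
  sc <- scenario_script(data.frame(start = 0, end = 10, pose = "standing",
                                   amplitude = 0), fps = 2, seed = 1)
  stream <- generate_skeleton_sequence(sc)
  angles <- vapply(unclass(stream), function(f) {
    extract_features(f$skeletons[[1]])$torso_angle
  }, numeric(1))
  expect_equal(angles, rep(0, length(stream)))
  truth <- attr(stream, "truth")
  expect_equal(unique(truth$pose), "standing")
})

test_that("scripts are validated", {
  expect_error(scenario_script(data.frame(start = 0, end = 0,
                                          pose = "standing")), "exceed")
  expect_error(scenario_script(data.frame(start = c(0, 5), end = c(10, 15),
                                          pose = "standing")), "overlap")
  expect_error(scenario_script(data.frame(start = 0, end = 10,
                                          pose = "jumping")), "unknown pose")
})

test_that("vitals follow the scripted sleep and dropout structure", {
  seg <- data.frame(start = 0, end = 7200, pose = "sleeping", amplitude = 0)
  sc_nosleep <- scenario_script(seg, seed = 2)
  v <- generate_vitals(sc_nosleep, sample_interval = 300)
  expect_false(any(v$sleep_state))

  sc_sleep <- scenario_script(seg, seed = 2,
                              sleep_intervals = data.frame(start = 0,
                                                           end = 3600))
  v2 <- generate_vitals(sc_sleep, sample_interval = 300)
  expect_true(all(v2$sleep_state[v2$timestamp < 3600]))
  expect_false(any(v2$sleep_state[v2$timestamp >= 3600]))
  # scripted sleep lowers heart rate by the scripted drop
  expect_lt(mean(v2$heart_rate[v2$sleep_state]),
            mean(v2$heart_rate[!v2$sleep_state]) - 5)

  # dropout probability 1 blanks every measurement (LOCF stress case)
  v3 <- generate_vitals(sc_nosleep, sample_interval = 300, dropout_prob = 1)
  expect_true(all(is.na(v3$heart_rate)))
  expect_true(all(is.na(v3$sleep_state)))
})

test_that("mean awake heart rate honours the scripted baseline", {
  # 7 whole days sampled every minute: > 10,000 samples, circadian term
  # averages out
  seg <- data.frame(start = 0, end = 7 * 86400, pose = "lying_in_bed",
                    amplitude = 0)
  sc <- scenario_script(seg, baseline_hr = 72, seed = 3)
  v <- generate_vitals(sc, sample_interval = 60)
  expect_gt(nrow(v), 10000)
  expect_equal(mean(v$heart_rate), 72, tolerance = 2 / 72)
})

test_that("generated patient states validate and carry oracle labels", {
  rs <- load_ruleset(demo_ruleset_path())
  recs <- generate_patient_states(200, rs, seed = 8)
  for (r in recs[1:20]) expect_true(validate_patient_state(r$state))
  # labels match a direct rule-engine sweep
  relabel <- vapply(recs, function(r) evaluate_rules(r$state, rs)$action,
                    character(1))
  expect_equal(vapply(recs, `[[`, character(1), "action"), relabel)
  # all four actions reachable under uniform sampling at this n
  expect_setequal(unique(relabel), plan_actions())
})

test_that("identity textures are more self-similar than cross-identity", {
  imgs <- generate_ward_images(identities = 3, per_class = 6, seed = 9)
  labels <- vapply(imgs, `[[`, character(1), "label")
  desc <- lapply(imgs, function(r) extract_descriptors(r$image))
  vocab <- build_vocabulary(do.call(rbind, desc), k = 16, seed = 9)
  hists <- t(vapply(desc, encode_descriptors, numeric(16),
                    vocabulary = vocab))
  cossim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  same <- c(); cross <- c()
  for (i in seq_along(imgs)) {
    for (j in seq_along(imgs)) {
      if (i >= j) next
      s <- cossim(hists[i, ], hists[j, ])
      if (labels[i] == labels[j] && labels[i] != "None") {
        same <- c(same, s)
      } else if (labels[i] != labels[j]) {
        cross <- c(cross, s)
      }
    }
  }
  expect_gt(mean(same), mean(cross))
})

test_that("ward image generation enforces its preconditions", {
  expect_error(generate_ward_images(identities = 4), "at most 3")
  expect_error(generate_ward_images(per_class = 1), "per_class")
})

test_that("scenario scripts round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "subject: patientA",
    "fps: 5",
    "seed: 12",
    "baseline_hr: 68",
    "noise_sd: 0.01",
    "segments:",
    "  - {start: 0, end: 60, pose: standing}",
    "  - {start: 60, end: 120, pose: walking, amplitude: 0.5}",
    "sleep_intervals:",
    "  - {start: 0, end: 30}"), path)
  sc <- read_scenario_yaml(path)
  expect_equal(sc$subject, "patientA")
  expect_equal(nrow(sc$segments), 2)
  expect_equal(sc$segments$amplitude[2], 0.5)
  expect_equal(sc$sleep_intervals$end, 30)
  expect_length(generate_skeleton_sequence(sc), 600)
  unlink(path)
})
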