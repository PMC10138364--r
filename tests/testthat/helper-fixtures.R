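# Shared fixtures, built in code.

# skeleton from a 17 x 2 coordinate matrix in canonical landmark order
make_skeleton <- function(coords, t = 0, person = "p1", conf = 0.95) {
  if (length(conf) == 1) conf <- rep(conf, 17)
  skeleton(data.frame(name = keypoint_names(),
                      x = coords[, 1], y = coords[, 2],
                      confidence = conf, stringsAsFactors = FALSE),
           timestamp = t, person_tag = person)
}

# upright stick figure (torso length `s` px) with mid-hip at `origin`
standing_coords <- function(s = 80, origin = c(100, 200)) {
  m <- rbind(
    c(0, -1.25), c(-0.04, -1.30), c(0.04, -1.30), c(-0.08, -1.28),
    c(0.08, -1.28), c(-0.12, -1.0), c(0.12, -1.0), c(-0.16, -0.55),
    c(0.16, -0.55), c(-0.18, -0.10), c(0.18, -0.10), c(-0.10, 0),
    c(0.10, 0), c(-0.11, 0.55), c(0.11, 0.55), c(-0.12, 1.10),
    c(0.12, 1.10))
  sweep(m * s, 2, origin, `+`)
}

# a small random frame stream for round-trip tests
random_stream <- function(n_frames = 5, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    n_sk <- sample(0:2, 1)
    sks <- lapply(seq_len(n_sk), function(j) {
      make_skeleton(standing_coords() + matrix(rnorm(34, 0, 5), 17, 2),
                    t = i * 0.1, person = paste0("p", j),
                    conf = runif(17))
    })
    frame_record(i * 0.1, sks,
                 lighting = sample(c("well_lit", "semi_lit", "poorly_lit"), 1))
  })
  frame_stream(frames)
}

# flat comparison of two streams on the data model
expect_stream_equal <- function(a, b, tol = 1e-8) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_equal(a[[i]]$timestamp, b[[i]]$timestamp, tolerance = tol)
    expect_equal(a[[i]]$lighting, b[[i]]$lighting)
    expect_equal(length(a[[i]]$skeletons), length(b[[i]]$skeletons))
    for (j in seq_along(a[[i]]$skeletons)) {
      sa <- a[[i]]$skeletons[[j]]; sb <- b[[i]]$skeletons[[j]]
      expect_equal(sa$person_tag, sb$person_tag)
      expect_equal(sa$keypoints$x, sb$keypoints$x, tolerance = tol)
      expect_equal(sa$keypoints$y, sb$keypoints$y, tolerance = tol)
      expect_equal(sa$keypoints$confidence, sb$keypoints$confidence,
                   tolerance = tol)
    }
  }
}

# a valid baseline patient state; override fields as needed
base_state <- function(...) {
  overrides <- list(...)
  schema <- patient_state_schema()
  vars <- lapply(schema, `[[`, 1)
  vars[["RiskC"]] <- "none"
  vars[["Pain"]] <- "none"
  vars[["Con"]] <- "unchanged"
  vars[["MoveH"]] <- "unchanged"
  vars[["Bedsores"]] <- "no"
  vars[["Breath"]] <- "normal"
  vars[["Temp"]] <- "36.0_37.4"
  vars[["Sat"]] <- "ge94"
  vars[["Gly"]] <- "ge2.5"
  vars[["BP"]] <- "normotension"
  vars[["PL"]] <- "normal"
  vars[["Urine"]] <- "normal"
  vars[["Fluid"]] <- "ge500ml"
  vars[["Sleep"]] <- "6_8h"
  vars[["Bowel"]] <- "regular"
  vars[["BMI"]] <- "stable"
  for (nm in names(overrides)) vars[[nm]] <- overrides[[nm]]
  patient_state(vars)
}

# labelled static-pose feature benchmark from the synthetic generator
posture_benchmark <- function(noise, occl, seed, seconds = 150) {
  poses <- c(standing = "upright", sitting = "sitting",
             lying_in_bed = "lying_like", fallen_on_ground = "fallen_on_ground")
  out <- list()
  for (p in names(poses)) {
    sc <- scenario_script(data.frame(start = 0, end = seconds, pose = p,
                                     amplitude = 0),
                          fps = 1, noise_sd = noise, occlusion_prob = occl,
                          seed = seed)
    st <- generate_skeleton_sequence(sc)
    for (f in unclass(st)) {
      out[[length(out) + 1L]] <- list(
        features = extract_features(f$skeletons[[1]],
                                    bed_region = sc$bed_region),
        pose = poses[[p]])
    }
    seed <- seed + 1
  }
  out
}
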