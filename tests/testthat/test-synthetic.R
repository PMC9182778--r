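simple_config <- function(...) {
  sim_config(scripts = data.frame(activity = 7L, duration = 2),
             n_videos = 1, ...)
}

test_that("the same seed reproduces the simulated stream exactly", {
  cfg <- simple_config(seed = 1)
  a <- simulate_track(cfg$scripts[[1]], cfg, seed = 9)
  b <- simulate_track(cfg$scripts[[1]], cfg, seed = 9)
  expect_identical(a, b)
  c <- simulate_track(cfg$scripts[[1]], cfg, seed = 10)
  expect_false(identical(a, c))
})

test_that("frame counts follow the script duration at the configured fps", {
  cfg <- sim_config(scripts = data.frame(activity = 6L, duration = 10),
                    n_videos = 1, empty_frame_prob = 0)
  sim <- simulate_track(cfg$scripts[[1]], cfg, seed = 2)
  expect_length(sim$frames, 180)            # 10 s at 18 fps
  expect_equal(nrow(sim$labels), 180)
  expect_true(all(sim$labels$label == 6L))
})

test_that("fall motifs descend monotonically on the noiseless template", {
  for (act in 1:5) {
    ts <- seq(0, 2.5, by = 1 / 18)
    mean_y <- vapply(ts, function(t) mean(motif_pose(act, t)[, "y"]),
                     numeric(1))
    expect_true(all(diff(mean_y) >= -1e-9))
    # descent complete well inside a second (the chair-landing fall
    # ends higher than the floor falls, hence the looser margin)
    expect_gt(mean_y[length(mean_y)], mean_y[1] + 50)
  }
  expect_error(motif_pose(13, 0), "unknown activity")
})

test_that("lying down shares endpoints with the sideways fall but not pace", {
  expect_equal(motif_pose(11, 0), motif_pose(5, 0))      # both start standing
  expect_equal(motif_pose(11, 2), motif_pose(5, 2))      # both end lying
  # half a second in, the fall is down and the lie-down is not
  y_fall <- mean(motif_pose(5, 0.5)[, "y"])
  y_lie <- mean(motif_pose(11, 0.5)[, "y"])
  expect_gt(y_fall, y_lie + 50)
})

test_that("generated files conform to the pose-result and label formats", {
  cfg <- sim_config(scripts = data.frame(activity = c(5L, 11L),
                                         duration = c(1.5, 1.5)),
                    n_videos = 3, seed = 4)
  dir <- withr::local_tempdir()
  manifest <- simulate_dataset(cfg, dir)
  expect_equal(nrow(manifest), 3)
  for (i in seq_len(nrow(manifest))) {
    frames <- parse_pose_results(manifest$pose_file[i])
    labels <- read_frame_labels(manifest$label_file[i])
    tr <- build_track(frames, labels, fps = manifest$fps[i])
    expect_gt(tr$n_frames, 0)
    expect_equal(ncol(tr$features), 51)
  }
})

test_that("stable bytes across repeated dataset generation", {
  cfg <- simple_config(seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_dataset(cfg, d1)
  m2 <- simulate_dataset(cfg, d2)
  expect_identical(readLines(m1$pose_file[1]), readLines(m2$pose_file[1]))
  expect_identical(readLines(m1$label_file[1]), readLines(m2$label_file[1]))
})

test_that("the score filter recovers the volunteer under full distraction", {
  cfg <- sim_config(scripts = data.frame(activity = 11L, duration = 2),
                    n_videos = 1, distractor_prob = 1, score_gap = 0.5,
                    empty_frame_prob = 0, seed = 5)
  sim <- simulate_track(cfg$scripts[[1]], cfg, seed = 5)
  for (fr in sim$frames) {
    expect_length(fr$detections, 2)
    picked <- select_person_of_interest(fr)
    # label-free identity check: the volunteer is the first record
    expect_identical(picked$keypoints, fr$detections[[1]]$keypoints)
  }
})

test_that("empty frames appear at the configured binomial rate", {
  cfg <- sim_config(scripts = data.frame(activity = 7L, duration = 56),
                    n_videos = 1, empty_frame_prob = 0.1,
                    distractor_prob = 0, seed = 6)
  sim <- simulate_track(cfg$scripts[[1]], cfg, seed = 6)
  n <- length(sim$frames)                    # 1008 frames
  retained <- sum(vapply(sim$frames, function(f) length(f$detections) > 0,
                         logical(1)))
  # 99% binomial bounds around 0.9 * n
  sdv <- sqrt(n * 0.1 * 0.9)
  expect_gt(retained, 0.9 * n - 2.58 * sdv)
  expect_lt(retained, 0.9 * n + 2.58 * sdv)
})

test_that("zero noise gives a perfect windowed classifier (sanity ceiling)", {
  cfg <- confusable_pair_config(n_videos = 12, noise_sd = 0,
                                distractor_prob = 0, empty_frame_prob = 0,
                                seed = 7)
  trks <- simulate_tracks(cfg)
  fm <- bind_feature_matrices(lapply(trks, build_feature_matrix,
                                     spec = window_spec(18, 2, 3)))
  # noiseless coordinates make the mid-window skeleton exactly
  # separable; a forest finds the separating coordinate deterministically
  rep <- run_protocol(fm, model = "rf", task = "activity",
                      rounds = 3, seed = 1)
  expect_equal(unname(rep$mean["recall"]), 100)
})

test_that("overwhelming noise drives recall toward the chance floor", {
  cfg <- confusable_pair_config(n_videos = 6, noise_sd = 1e5,
                                distractor_prob = 0, empty_frame_prob = 0,
                                seed = 8)
  trks <- simulate_tracks(cfg)
  fm <- bind_feature_matrices(lapply(trks, build_feature_matrix,
                                     spec = window_spec(18, 2, 3)))
  rep <- run_protocol(fm, model = "knn", task = "activity",
                      rounds = 5, seed = 1)
  expect_lt(unname(rep$mean["recall"]), 80)
})

test_that("unknown activity ids in a script are rejected", {
  expect_error(sim_config(scripts = data.frame(activity = 99L, duration = 1),
                          n_videos = 1),
               "unknown activity")
})
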