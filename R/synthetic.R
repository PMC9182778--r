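# Synthetic labelled skeleton sequences. A 17-joint stick figure (COCO
# order: nose, eyes, ears, shoulders, elbows, wrists, hips, knees,
# ankles) follows an activity-specific parametric motif; frames carry
# per-joint scores and an overall detection score, optional distractor
# people and occasional empty frames, so the generated streams exercise
# the whole pipeline in the exact external formats of the I/O layer.

# Canonical postures in a 640 x 480 image (pixels, origin top-left, y
# grows downward). One column per coordinate, COCO joint order by row.
.template <- function(xy) {
  m <- matrix(xy, ncol = 2L, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

TEMPLATE_STANDING <- .template(c(
  320, 100,   # nose
  312,  92,  328,  92,   # eyes
  306,  98,  334,  98,   # ears
  295, 150,  345, 150,   # shoulders
  285, 210,  355, 210,   # elbows
  280, 265,  360, 265,   # wrists
  305, 260,  335, 260,   # hips
  300, 350,  340, 350,   # knees
  298, 440,  342, 440))  # ankles

TEMPLATE_LYING <- .template(c(
  170, 428,
  163, 421,  163, 435,
  156, 423,  156, 433,
  210, 418,  210, 442,
  250, 414,  250, 446,
  285, 412,  285, 448,
  310, 424,  310, 440,
  380, 426,  380, 442,
  450, 428,  450, 440))

TEMPLATE_SITTING <- .template(c(
  320, 230,
  312, 222,  328, 222,
  306, 228,  334, 228,
  295, 275,  345, 275,
  290, 325,  350, 325,
  295, 360,  345, 360,
  305, 350,  335, 350,
  365, 355,  390, 358,
  368, 440,  392, 440))

# descent progress d(t) in [0, 1] and target posture per activity;
# oscillation/drift terms are added on top of the blended posture
.motif_table <- function() {
  fall <- function(t) pmin(1, t / 0.45)   # rapid descent, ~0.45 s
  list(
    `1` = list(d = fall, target = "lying", x_off = -50),  # fall forward, hands
    `2` = list(d = fall, target = "lying", x_off = -25),  # fall forward, knees
    `3` = list(d = fall, target = "lying", x_off = 25),   # fall backward
    `4` = list(d = fall, target = "sitting", x_off = 0),  # land sitting on chair
    `5` = list(d = fall, target = "lying", x_off = 0),    # fall sideways
    `6` = list(d = function(t) 0, target = "lying",       # walking
               drift = 40, swing_amp = 15, swing_period = 0.8),
    `7` = list(d = function(t) 0, target = "lying",       # standing
               sway_amp = 2, sway_period = 2),
    `8` = list(d = function(t) 0.55 * sin(pi * (t %% 2) / 2)^2,
               target = "lying"),                         # pick up an object
    `9` = list(d = function(t) pmin(1, t / 1.0),
               target = "sitting"),                       # sit
    `10` = list(d = function(t) 0, target = "lying",      # jump
                bounce_amp = 30, bounce_period = 0.9),
    `11` = list(d = function(t) pmin(1, t / 1.5),
                target = "lying"),                        # lie down (slow descent)
    `12` = list(d = function(t) 0.5 * pmin(1, t / 0.8),
                target = "lying")                         # kneel (half descent)
  )
}

#' Noise-free skeleton posture of an activity motif
#'
#' Evaluates the parametric trajectory template of one activity at
#' elapsed time `t` within the activity segment: a blend between the
#' standing posture and the motif's target posture, with the motif's
#' oscillation (gait swing, sway, jump bounce) and horizontal drift
#' added. Fall motifs descend to the ground in about 0.45 s while the
#' lying-down motif takes 1.5 s, so the two classes share their start
#' and end postures and differ only in descent dynamics.
#'
#' @param activity Activity id in 1--12.
#' @param t Elapsed time within the segment, seconds.
#' @return Numeric 17 x 2 matrix of (x, y) pixel coordinates in COCO
#'   joint order.
#' @export
motif_pose <- function(activity, t) {
  motifs <- .motif_table()
  m <- motifs[[as.character(as.integer(activity))]]
  if (is.null(m)) {
    stop(sprintf("unknown activity id %s", activity), call. = FALSE)
  }
  target <- switch(m$target, lying = TEMPLATE_LYING,
                   sitting = TEMPLATE_SITTING)
  d <- m$d(t)
  pose <- (1 - d) * TEMPLATE_STANDING + d * target
  if (!is.null(m$x_off)) pose[, "x"] <- pose[, "x"] + d * m$x_off
  if (!is.null(m$drift)) pose[, "x"] <- pose[, "x"] + m$drift * t
  if (!is.null(m$swing_amp)) {
    # alternating leg/arm swing: left and right limbs in antiphase
    ph <- sin(2 * pi * t / m$swing_period)
    left <- c(14, 16, 10)   # left knee, ankle, wrist
    right <- c(15, 17, 11)
    pose[left, "x"] <- pose[left, "x"] + m$swing_amp * ph
    pose[right, "x"] <- pose[right, "x"] - m$swing_amp * ph
  }
  if (!is.null(m$sway_amp)) {
    pose[, "x"] <- pose[, "x"] + m$sway_amp * sin(2 * pi * t / m$sway_period)
  }
  if (!is.null(m$bounce_amp)) {
    pose[, "y"] <- pose[, "y"] - m$bounce_amp * abs(sin(2 * pi * t / m$bounce_period))
  }
  pose
}

#' Simulation configuration
#'
#' @param scripts List with one activity script per video; each script
#'   is a data frame with columns `activity` (id in 1--12) and
#'   `duration` (seconds). A single data frame is recycled for all
#'   videos.
#' @param n_videos Number of videos (default: length of `scripts`).
#' @param fps Frames per second (default 18, the frame rate of the
#'   benchmark videos the method targets).
#' @param noise_sd Gaussian pixel noise added to every keypoint
#'   coordinate (default 2).
#' @param distractor_prob Per-frame probability that a second,
#'   lower-scored person appears (default 0.2).
#' @param score_gap Expected gap between the volunteer's and a
#'   distractor's overall score (default 0.3).
#' @param empty_frame_prob Per-frame probability that the detector
#'   returns no people (default 0.02).
#' @param seed Base seed; video `v` is generated from `seed + v`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scripts, n_videos = length(scripts), fps = 18L,
                       noise_sd = 2, distractor_prob = 0.2,
                       score_gap = 0.3, empty_frame_prob = 0.02,
                       seed = 1L) {
  if (is.data.frame(scripts)) scripts <- list(scripts)
  if (n_videos < 1L) stop("`n_videos` must be >= 1", call. = FALSE)
  scripts <- rep_len(scripts, n_videos)
  for (s in scripts) {
    stopifnot(is.data.frame(s), all(c("activity", "duration") %in% names(s)))
    if (any(s$duration <= 0)) stop("script durations must be positive",
                                   call. = FALSE)
    bad <- setdiff(s$activity, activity_vocabulary())
    if (length(bad)) stop(sprintf("unknown activity id %d in script", bad[1L]),
                          call. = FALSE)
  }
  stopifnot(fps >= 1, noise_sd >= 0,
            distractor_prob >= 0, distractor_prob <= 1,
            empty_frame_prob >= 0, empty_frame_prob <= 1)
  structure(list(scripts = scripts, n_videos = as.integer(n_videos),
                 fps = as.integer(fps), noise_sd = noise_sd,
                 distractor_prob = distractor_prob, score_gap = score_gap,
                 empty_frame_prob = empty_frame_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Confusable fall / lie-down study configuration
#'
#' The dataset at the heart of the temporal-context property: half the
#' videos perform a sideways fall (id 5, descent in about 0.45 s) and
#' half lie down (id 11, descent over 1.5 s). Start and end postures
#' are identical between the two classes, so single frames are
#' ambiguous wherever the subject is down, while a 2-second window
#' resolves the descent dynamics.
#'
#' @param n_videos Total videos, alternating fall / lie-down
#'   (default 20, giving about 200 two-second windows at 18 fps).
#' @param duration Seconds per video (default 2.5, long enough for one
#'   2-s window plus slide).
#' @param ... Passed on to [sim_config()] (noise, distractors, seed...).
#' @return A [sim_config()].
#' @export
confusable_pair_config <- function(n_videos = 20L, duration = 2.5, ...) {
  scripts <- lapply(seq_len(n_videos), function(v) {
    data.frame(activity = if (v %% 2L == 1L) 5L else 11L,
               duration = duration)
  })
  sim_config(scripts = scripts, n_videos = n_videos, ...)
}

.joint_scores <- function() stats::runif(N_KEYPOINTS, 0.75, 0.95)

#' Simulate one video's pose stream
#'
#' One frame per tick at the configured fps. The volunteer's skeleton
#' follows the active script entry's motif with additive Gaussian
#' keypoint noise; the overall detection score is the mean joint score.
#' Distractor people (a standing figure offset to the side), when drawn,
#' receive an overall score lower by the configured gap, so the
#' person-of-interest filter recovers the volunteer. Empty frames are
#' inserted with the configured probability; the label table still
#' covers them.
#'
#' @param script Data frame with columns `activity`, `duration`.
#' @param config A [sim_config()] (its `scripts` field is ignored here).
#' @param seed Seed for this track; same seed, same stream.
#' @return List with `frames` (list of [frame_detections()]) and
#'   `labels` (a [frame_labels()] table, one row per frame).
#' @export
simulate_track <- function(script, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  fps <- config$fps
  per_entry <- as.integer(floor(script$duration * fps + 0.5))
  frames <- list()
  lab_frame <- integer(0)
  lab_id <- integer(0)
  frame_i <- 0L
  for (e in seq_len(nrow(script))) {
    act <- as.integer(script$activity[e])
    for (j in seq_len(per_entry[e]) - 1L) {
      t <- j / fps
      lab_frame <- c(lab_frame, frame_i)
      lab_id <- c(lab_id, act)
      if (stats::runif(1) < config$empty_frame_prob) {
        frames[[length(frames) + 1L]] <- frame_detections(frame_i)
        frame_i <- frame_i + 1L
        next
      }
      pose <- motif_pose(act, t)
      pose <- pose + matrix(stats::rnorm(N_KEYPOINTS * 2L,
                                         sd = config$noise_sd),
                            N_KEYPOINTS, 2L)
      js <- .joint_scores()
      vol <- pose_detection(cbind(pose, js), score = mean(js))
      dets <- list(vol)
      if (stats::runif(1) < config$distractor_prob) {
        dpose <- TEMPLATE_STANDING
        dpose[, "x"] <- dpose[, "x"] + 150
        dpose <- dpose + matrix(stats::rnorm(N_KEYPOINTS * 2L,
                                             sd = config$noise_sd),
                                N_KEYPOINTS, 2L)
        djs <- pmax(.joint_scores() - config$score_gap, 0.01)
        dist <- pose_detection(cbind(dpose, djs),
                               score = max(mean(js) - config$score_gap, 0.01))
        dets <- c(dets, list(dist))
      }
      frames[[length(frames) + 1L]] <- frame_detections(frame_i, dets)
      frame_i <- frame_i + 1L
    }
  }
  list(frames = frames,
       labels = frame_labels(lab_frame, lab_id))
}

#' Simulate a dataset of pose-result and label files
#'
#' Writes one AlphaPose-convention JSON result file and one
#' `frame,label` CSV per video, in exactly the formats consumed by
#' [parse_pose_results()] and [read_frame_labels()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Data frame manifest: `video_id`, `pose_file`, `label_file`,
#'   `fps`.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- lapply(seq_len(config$n_videos), function(v) {
    sim <- simulate_track(config$scripts[[v]], config,
                          seed = config$seed + v)
    vid <- sprintf("video%02d", v)
    pf <- file.path(dir, paste0(vid, ".json"))
    lf <- file.path(dir, paste0(vid, "_labels.csv"))
    write_pose_results(sim$frames, pf)
    write_frame_labels(sim$labels, lf)
    data.frame(video_id = vid, pose_file = pf, label_file = lf,
               fps = config$fps)
  })
  do.call(rbind, manifest)
}

#' Simulate and build clean tracks directly
#'
#' Convenience wrapper for in-memory pipelines: simulates each video,
#' applies the person-of-interest filter and empty-frame removal, and
#' returns the resulting tracks.
#'
#' @param config A [sim_config()].
#' @return List of `pose_track` objects, one per video.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lapply(seq_len(config$n_videos), function(v) {
    sim <- simulate_track(config$scripts[[v]], config,
                          seed = config$seed + v)
    build_track(sim$frames, sim$labels, fps = config$fps,
                video_id = sprintf("video%02d", v))
  })
}
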