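# Independent brute-force references and fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

# a pose_track with random skeleton features and labels, built directly
random_track <- function(n_frames, fps = 18L, labels = NULL,
                         video_id = "rand") {
  if (is.null(labels)) labels <- sample(1:12, n_frames, replace = TRUE)
  structure(list(video_id = video_id, fps = as.integer(fps),
                 frame_index = seq_len(n_frames) - 1L,
                 labels = as.integer(labels),
                 features = matrix(rnorm(n_frames * 51), n_frames, 51),
                 n_frames = as.integer(n_frames)),
            class = "pose_track")
}

# feature_matrix built directly from a plain matrix + labels
fm_of <- function(features, labels) {
  skelwin::feature_matrix(features, labels)
}

# mode with smallest-id tie-break, by explicit counting
oracle_mode <- function(labels) {
  ids <- sort(unique(labels))
  counts <- vapply(ids, function(u) sum(labels == u), integer(1))
  ids[counts == max(counts)][1L]
}

# evenly spaced offsets: exact floor of k/(S-1) * (SWL-1), found by
# scanning candidate integers so no floating-point division is involved
oracle_offsets <- function(SWL, S) {
  first <- vapply(0:(S - 2), function(k) {
    m <- 0
    while ((m + 1) * (S - 1) <= k * (SWL - 1)) m <- m + 1
    m
  }, numeric(1))
  c(first, SWL - 1)
}

# window length by direct formula
oracle_swl <- function(fps, W) max(2, floor(fps * W + 0.5))

# materialize every window and copy values element by element
oracle_feature_matrix <- function(track, W, S) {
  SWL <- oracle_swl(track$fps, W)
  offs <- oracle_offsets(SWL, S)
  n_win <- track$n_frames - SWL + 1
  if (n_win < 1) {
    return(list(features = matrix(numeric(0), 0, 51 * S),
                labels = integer(0)))
  }
  out <- matrix(NA_real_, n_win, 51 * S)
  labs <- integer(n_win)
  for (i in seq_len(n_win)) {
    row <- numeric(0)
    for (o in offs) row <- c(row, track$features[i + o, ])
    out[i, ] <- row
    labs[i] <- oracle_mode(track$labels[i:(i + SWL - 1)])
  }
  list(features = out, labels = labs)
}

# metric formulas computed directly from the counts
oracle_metrics <- function(TP, FP, TN, FN) {
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- div(TP, TP + FP)
  rec <- div(TP, TP + FN)
  100 * c(accuracy = (TP + TN) / (TP + FP + TN + FN),
          precision = prec,
          recall = rec,
          specificity = div(TN, TN + FP),
          f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# a single pose_detection with given score and uniform keypoints
make_det <- function(score, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kp <- cbind(runif(17, 0, 640), runif(17, 0, 480), runif(17))
  skelwin::pose_detection(kp, score)
}
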