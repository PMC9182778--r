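# Reduction of raw multi-person frames to a clean one-skeleton-per-frame
# track: keep the highest-scoring detection per frame, drop empty frames.

#' Select the person of interest in a frame
#'
#' Multi-person frames are reduced to the detection with the highest
#' overall score; distractor skeletons are discarded. Ties are broken by
#' file order (the earlier record wins), which keeps the reduction
#' deterministic.
#'
#' @param frame A [frame_detections()].
#' @return The winning [pose_detection()], or `NULL` for an empty frame
#'   (absence is a value, not an error).
#' @export
select_person_of_interest <- function(frame) {
  stopifnot(inherits(frame, "frame_detections"))
  if (length(frame$detections) == 0L) return(NULL)
  scores <- vapply(frame$detections, `[[`, numeric(1), "score")
  frame$detections[[which.max(scores)]]
}

#' Build a clean per-video pose track
#'
#' Applies the person-of-interest filter to every frame, removes empty
#' frames, and attaches the frame label to each retained skeleton. After
#' removal the retained frames are treated as temporally consecutive for
#' windowing; original frame indices are kept for traceability only.
#'
#' @param frames List of [frame_detections()] (any order; sorted by
#'   frame index internally).
#' @param labels A [frame_labels()] table covering every non-empty frame.
#' @param fps Frames per second of the source video (positive integer).
#' @param video_id Identifier for the video.
#' @return An object of class `pose_track`: a list with `video_id`,
#'   `fps`, `frame_index` (original indices, strictly increasing),
#'   `labels` (integer activity ids), `features` (n x 51 matrix of flat
#'   skeleton views) and `n_frames`.
#' @export
build_track <- function(frames, labels, fps, video_id = "video") {
  stopifnot(inherits(labels, "frame_labels"))
  fps <- as.integer(fps)
  if (is.na(fps) || fps < 1L) stop("`fps` must be a positive integer",
                                   call. = FALSE)
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  frames <- frames[order(idx)]
  kept_idx <- integer(0)
  kept_lab <- integer(0)
  rows <- list()
  for (fr in frames) {
    det <- select_person_of_interest(fr)
    if (is.null(det)) next
    pos <- match(fr$frame_index, labels$frame)
    if (is.na(pos)) {
      stop(sprintf("non-empty frame %d has no label", fr$frame_index),
           call. = FALSE)
    }
    kept_idx <- c(kept_idx, fr$frame_index)
    kept_lab <- c(kept_lab, labels$label[pos])
    rows[[length(rows) + 1L]] <- pose_features(det)
  }
  feats <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0L, N_FRAME_FEATURES)
  dimnames(feats) <- NULL
  structure(list(video_id = video_id, fps = fps,
                 frame_index = kept_idx, labels = kept_lab,
                 features = feats, n_frames = length(kept_idx)),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track '%s': %d frames @ %d fps, %d activity label%s>\n",
              x$video_id, x$n_frames, x$fps,
              length(unique(x$labels)),
              if (length(unique(x$labels)) == 1L) "" else "s"))
  invisible(x)
}

#' Write a pose track as CSV
#'
#' One row per retained frame: `frame,label,f0,...,f50`.
#'
#' @param track A [build_track()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "pose_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("frame", "label", sprintf("f%d", 0:50)),
                   collapse = ","), con)
  if (track$n_frames > 0L) {
    body <- vapply(seq_len(track$n_frames), function(i) {
      paste(c(track$frame_index[i], track$labels[i],
              sprintf("%.17g", track$features[i, ])), collapse = ",")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a pose track written by [write_track()]
#'
#' @param path CSV path.
#' @param fps Frames per second to attach (not stored in the CSV).
#' @param video_id Identifier to attach.
#' @return A `pose_track`.
#' @export
read_track <- function(path, fps, video_id = "video") {
  df <- utils::read.csv(path)
  need <- c("frame", "label", sprintf("f%d", 0:50))
  if (!identical(names(df), need)) {
    stop("track file must have columns frame,label,f0..f50", call. = FALSE)
  }
  feats <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(feats) <- NULL
  structure(list(video_id = video_id, fps = as.integer(fps),
                 frame_index = as.integer(df$frame),
                 labels = as.integer(df$label),
                 features = feats, n_frames = nrow(df)),
            class = "pose_track")
}
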