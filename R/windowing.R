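# Sliding-window construction: window length in frames, evenly spaced
# skeleton selection within the window, concatenated feature vectors,
# and mode labelling.

#' Sliding-window length in frames
#'
#' `SWL = fps * W`, rounded to the nearest integer (half away from
#' zero) with a floor of 2 so a window always spans at least two frames.
#' At the 18 fps used throughout, W = 0.5/1/2 s give SWL = 9/18/36.
#'
#' @param fps Frames per second (positive integer).
#' @param W Window duration in seconds (positive).
#' @return Integer window length in frames.
#' @export
compute_swl <- function(fps, W) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps < 1) {
    stop("`fps` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(W) || length(W) != 1L || is.na(W) || W <= 0) {
    stop("`W` must be a positive duration in seconds", call. = FALSE)
  }
  max(2L, as.integer(floor(fps * W + 0.5)))
}

#' Number of sliding windows in a video
#'
#' With stride one frame, a video of `n_frames` frames yields
#' `n_frames - SWL + 1` windows; a video shorter than the window yields
#' none (it is too short for this window duration and is skipped).
#'
#' @param n_frames Number of (cleaned) frames in the video.
#' @param SWL Window length in frames (>= 2).
#' @return Integer window count (0 when the video is too short).
#' @export
count_windows <- function(n_frames, SWL) {
  n_frames <- as.integer(n_frames)
  SWL <- as.integer(SWL)
  if (is.na(SWL) || SWL < 2L) stop("`SWL` must be >= 2", call. = FALSE)
  if (is.na(n_frames) || n_frames < 0L) {
    stop("`n_frames` must be non-negative", call. = FALSE)
  }
  max(0L, n_frames - SWL + 1L)
}

#' Evenly spaced skeleton offsets within a window
#'
#' Picks `S` frame offsets in `0..SWL-1`: offset `k` is
#' `floor(k / (S - 1) * (SWL - 1))` for `k = 0..S-2`, and the last
#' offset is pinned to `SWL - 1`, so the first and last frames of the
#' window are always included. For `S = 3` this is the first, middle and
#' last frame; for `S = SWL` every frame is selected.
#'
#' @param SWL Window length in frames.
#' @param S Number of skeletons per window, `2 <= S <= SWL`.
#' @return Strictly increasing integer vector of `S` offsets, starting
#'   at 0 and ending at `SWL - 1`.
#' @export
select_offsets <- function(SWL, S) {
  SWL <- as.integer(SWL)
  S <- as.integer(S)
  if (is.na(S) || S < 2L || S > SWL) {
    stop(sprintf("`S` must satisfy 2 <= S <= SWL (= %d)", SWL),
         call. = FALSE)
  }
  k <- 0:(S - 2L)
  # integer arithmetic avoids floating-point edge cases in the floor
  off <- (k * (SWL - 1L)) %/% (S - 1L)
  c(off, SWL - 1L)
}

#' Window configuration
#'
#' Bundles the window duration `W`, frame rate, derived window length
#' `SWL`, skeleton count `S`, the skeleton offsets, and the feature
#' vector length `F = 51 * S`.
#'
#' @param fps Frames per second.
#' @param W Window duration in seconds.
#' @param S Skeletons per window (`2 <= S <= SWL`). The frame-by-frame
#'   baseline (no window) is handled separately by
#'   [frame_feature_matrix()].
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(fps, W, S) {
  SWL <- compute_swl(fps, W)
  offsets <- select_offsets(SWL, S)
  structure(list(W = W, fps = as.integer(fps), SWL = SWL,
                 S = as.integer(S), offsets = offsets,
                 F = N_FRAME_FEATURES * as.integer(S)),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf(
    "<window_spec W=%gs @ %d fps: SWL=%d frames, S=%d skeletons, F=%d>\n",
    x$W, x$fps, x$SWL, x$S, x$F))
  invisible(x)
}

#' Mode label of a window
#'
#' The window's activity is the most frequent of its frame labels; ties
#' are broken toward the smallest label id, which in the 12-activity
#' vocabulary prefers fall classes and keeps the rule deterministic.
#'
#' @param labels Integer activity ids of the frames spanned by the
#'   window (at least one).
#' @return The modal label id.
#' @export
window_label <- function(labels) {
  if (length(labels) == 0L) stop("empty label window", call. = FALSE)
  counts <- table(labels)
  ids <- as.integer(names(counts))
  min(ids[counts == max(counts)])
}

#' Stacked window feature matrix
#'
#' Rows are windows; row `i` is the concatenation, in temporal order, of
#' the 51-value flat views of the `S` selected skeletons, and carries the
#' mode label of the frames the window spans.
#'
#' @param features Numeric matrix, one row per window, width `F`.
#' @param labels Integer label per row.
#' @param video Optional character vector naming the source video of
#'   each row; carried through pooling and used by video-level splits.
#' @return An object of class `feature_matrix` with elements `features`,
#'   `labels`, `video`, `n_windows` and `F`.
#' @export
feature_matrix <- function(features, labels, video = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("feature rows and labels differ in length", call. = FALSE)
  }
  if (is.null(video)) {
    video <- rep(NA_character_, length(labels))
  } else {
    video <- rep_len(as.character(video), length(labels))
  }
  dimnames(features) <- NULL
  structure(list(features = features, labels = labels, video = video,
                 n_windows = nrow(features), F = ncol(features)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d windows x %d features, %d class%s>\n",
              x$n_windows, x$F, length(unique(x$labels)),
              if (length(unique(x$labels)) == 1L) "" else "es"))
  invisible(x)
}

#' Bind feature matrices row-wise
#'
#' Pools windows across videos; all matrices must share the same width.
#'
#' @param ... `feature_matrix` objects (or a single list of them).
#' @return A pooled [feature_matrix()].
#' @export
bind_feature_matrices <- function(...) {
  fms <- list(...)
  if (length(fms) == 1L && !inherits(fms[[1L]], "feature_matrix")) {
    fms <- fms[[1L]]
  }
  stopifnot(all(vapply(fms, inherits, logical(1), "feature_matrix")))
  widths <- vapply(fms, `[[`, integer(1), "F")
  if (length(unique(widths)) > 1L) {
    stop("feature matrices have differing widths", call. = FALSE)
  }
  feature_matrix(do.call(rbind, lapply(fms, `[[`, "features")),
                 unlist(lapply(fms, `[[`, "labels")),
                 video = unlist(lapply(fms, `[[`, "video")))
}

#' Build the sliding-window feature matrix of a track
#'
#' Slides a window of `spec$SWL` frames over the cleaned track with
#' stride one. Window `i` (0-based start) concatenates the flat views of
#' the skeletons at frames `i + spec$offsets` and is labelled with the
#' mode of the frame labels `i .. i + SWL - 1`. A track shorter than the
#' window yields an empty matrix with a warning.
#'
#' @param track A [build_track()] result.
#' @param spec A [window_spec()]; its fps must match the track's.
#' @return A [feature_matrix()] with `count_windows(track$n_frames,
#'   spec$SWL)` rows of width `spec$F`.
#' @export
build_feature_matrix <- function(track, spec) {
  stopifnot(inherits(track, "pose_track"), inherits(spec, "window_spec"))
  if (track$fps != spec$fps) {
    stop(sprintf("track fps (%d) does not match window spec fps (%d)",
                 track$fps, spec$fps), call. = FALSE)
  }
  n_win <- count_windows(track$n_frames, spec$SWL)
  if (n_win == 0L) {
    warning(sprintf("track '%s' (%d frames) is shorter than the window (%d frames)",
                    track$video_id, track$n_frames, spec$SWL), call. = FALSE)
    return(feature_matrix(matrix(numeric(0), 0L, spec$F), integer(0)))
  }
  out <- matrix(NA_real_, n_win, spec$F)
  for (k in seq_along(spec$offsets)) {
    cols <- ((k - 1L) * N_FRAME_FEATURES + 1L):(k * N_FRAME_FEATURES)
    out[, cols] <- track$features[seq_len(n_win) + spec$offsets[k], ,
                                  drop = FALSE]
  }
  labs <- vapply(seq_len(n_win), function(i) {
    window_label(track$labels[i:(i + spec$SWL - 1L)])
  }, integer(1))
  feature_matrix(out, labs, video = track$video_id)
}

#' Frame-by-frame baseline feature matrix
#'
#' The predecessor representation the windowed method is compared
#' against: each frame's 51 skeleton features classified independently,
#' labelled with that frame's own activity (no window, no mode).
#'
#' @param track A [build_track()] result.
#' @return A [feature_matrix()] with `track$n_frames` rows of width 51.
#' @export
frame_feature_matrix <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  feature_matrix(track$features, track$labels, video = track$video_id)
}
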