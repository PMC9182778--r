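# Reading and writing the external representations: AlphaPose-style
# pose-result files, frame-label tables, and feature tables.

#' Construct a single-person pose detection
#'
#' A pose detection holds the 17 COCO keypoints of one person in one
#' frame, each as an (x, y, score) triple, plus the detector's overall
#' confidence for the whole skeleton. Coordinates are pixels with the
#' image origin at the top-left, so y grows downward.
#'
#' @param keypoints Numeric 17 x 3 matrix; columns are x, y and the joint
#'   confidence score in `[0, 1]`.
#' @param score Overall detection confidence (non-negative).
#' @return An object of class `pose_detection`.
#' @export
pose_detection <- function(keypoints, score) {
  keypoints <- as.matrix(keypoints)
  if (!is.numeric(keypoints) || nrow(keypoints) != N_KEYPOINTS ||
      ncol(keypoints) != 3L) {
    stop("`keypoints` must be a numeric 17 x 3 matrix", call. = FALSE)
  }
  if (anyNA(keypoints) || any(!is.finite(keypoints))) {
    stop("keypoint coordinates and scores must be finite", call. = FALSE)
  }
  s <- keypoints[, 3L]
  if (any(s < 0) || any(s > 1)) {
    warning("joint scores outside [0, 1] clamped", call. = FALSE)
    keypoints[, 3L] <- pmin(pmax(s, 0), 1)
  }
  score <- as.numeric(score)
  if (length(score) != 1L || is.na(score) || score < 0) {
    stop("`score` must be a single non-negative number", call. = FALSE)
  }
  colnames(keypoints) <- c("x", "y", "s")
  structure(list(keypoints = keypoints, score = score),
            class = "pose_detection")
}

#' Flat 51-value feature view of a pose detection
#'
#' Returns the keypoints in joint order as
#' `(x1, y1, s1, ..., x17, y17, s17)` — a pure reordering, no transform.
#'
#' @param pose A [pose_detection()].
#' @return Numeric vector of length 51.
#' @export
pose_features <- function(pose) {
  stopifnot(inherits(pose, "pose_detection"))
  as.vector(t(pose$keypoints))
}

#' Rebuild a pose detection from its flat feature view
#'
#' Inverse of [pose_features()]: reshapes 51 values back into the
#' 17 x 3 keypoint matrix.
#'
#' @param x Numeric vector of length 51.
#' @param score Overall detection score to attach.
#' @return A [pose_detection()].
#' @export
pose_from_features <- function(x, score = 1) {
  if (length(x) != N_FRAME_FEATURES) {
    stop("flat feature view must have exactly 51 values", call. = FALSE)
  }
  pose_detection(matrix(x, nrow = N_KEYPOINTS, ncol = 3L, byrow = TRUE),
                 score)
}

#' Container for all detections in one frame
#'
#' @param frame_index 0-based frame index.
#' @param detections List of [pose_detection()] objects; may be empty
#'   (an empty frame).
#' @return An object of class `frame_detections`.
#' @export
frame_detections <- function(frame_index, detections = list()) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L) {
    stop("`frame_index` must be a non-negative integer", call. = FALSE)
  }
  if (!all(vapply(detections, inherits, logical(1), "pose_detection"))) {
    stop("`detections` must be a list of pose_detection objects",
         call. = FALSE)
  }
  structure(list(frame_index = frame_index, detections = detections),
            class = "frame_detections")
}

# "123.jpg" -> 123L; "img_007.png" -> 7L. Errors when no trailing integer.
frame_index_from_image <- function(image_id) {
  stem <- sub("\\.[A-Za-z0-9]+$", "", image_id)
  m <- regmatches(stem, regexpr("[0-9]+$", stem))
  if (length(m) == 0L || !nzchar(m)) {
    stop(sprintf("cannot parse a frame index from image id '%s'", image_id),
         call. = FALSE)
  }
  as.integer(m)
}

#' Parse a pose-estimation result file
#'
#' Reads the AlphaPose single-file result convention: a JSON array of
#' records, each with an `image_id` (frame image name), a flat
#' `keypoints` list of 51 numbers (`x, y, score` for each of the 17 COCO
#' joints) and an overall detection `score`. Records are grouped by
#' frame; frames are returned in ascending frame-index order. Frame
#' indices are taken from the trailing integer of the image name stem.
#'
#' @param path Path to the JSON result file.
#' @return A list of [frame_detections()], ordered by frame index. Only
#'   frames with at least one record appear; downstream code treats
#'   missing indices as empty frames.
#' @export
parse_pose_results <- function(path) {
  records <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(records)) stop("pose result file must be a JSON array",
                              call. = FALSE)
  frames <- new.env(parent = emptyenv())
  for (rec in records) {
    if (is.null(rec$image_id)) {
      stop("pose record without an image_id", call. = FALSE)
    }
    idx <- frame_index_from_image(rec$image_id)
    kp <- unlist(rec$keypoints, use.names = FALSE)
    if (length(kp) != N_FRAME_FEATURES || !is.numeric(kp)) {
      stop(sprintf("frame %d: keypoint list has %d values, expected 51",
                   idx, length(kp)), call. = FALSE)
    }
    sc <- rec$score
    if (is.null(sc) || !is.numeric(sc) || length(sc) != 1L || is.na(sc)) {
      stop(sprintf("frame %d: non-numeric detection score", idx),
           call. = FALSE)
    }
    det <- pose_from_features(kp, score = sc)
    key <- as.character(idx)
    frames[[key]] <- c(if (!is.null(frames[[key]])) frames[[key]], list(det))
  }
  idxs <- sort(as.integer(ls(frames)))
  lapply(idxs, function(i) frame_detections(i, frames[[as.character(i)]]))
}

#' Write pose detections in the AlphaPose result-file convention
#'
#' Counterpart of [parse_pose_results()]; used by the synthetic generator
#' and useful for fixtures.
#'
#' @param frames List of [frame_detections()].
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_pose_results <- function(frames, path) {
  records <- list()
  for (fr in frames) {
    for (det in fr$detections) {
      records[[length(records) + 1L]] <- list(
        image_id = sprintf("%d.jpg", fr$frame_index),
        category_id = 1L,
        keypoints = as.list(pose_features(det)),
        score = det$score
      )
    }
  }
  jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a frame-label table
#'
#' Labels come as a delimited text table with header `frame,label`,
#' one row per frame, frame indices 0-based.
#'
#' @param path Path to the CSV file.
#' @param vocabulary Allowed label ids; defaults to the 12-activity
#'   vocabulary ([activity_vocabulary()]).
#' @return A data frame of class `frame_labels` with integer columns
#'   `frame` and `label`, sorted by frame.
#' @export
read_frame_labels <- function(path, vocabulary = activity_vocabulary()) {
  df <- utils::read.csv(path, colClasses = "integer")
  frame_labels(df$frame, df$label, vocabulary = vocabulary)
}

#' Construct a frame-label table from vectors
#'
#' @param frame Integer frame indices (0-based, unique).
#' @param label Integer activity ids, same length as `frame`.
#' @param vocabulary Allowed label ids.
#' @return A data frame of class `frame_labels`, sorted by frame.
#' @export
frame_labels <- function(frame, label, vocabulary = activity_vocabulary()) {
  frame <- as.integer(frame)
  label <- as.integer(label)
  if (length(frame) != length(label)) {
    stop("`frame` and `label` lengths differ", call. = FALSE)
  }
  if (anyNA(frame) || any(frame < 0L)) {
    stop("frame indices must be non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(frame)) {
    dup <- frame[duplicated(frame)][1L]
    stop(sprintf("duplicate frame index %d in label table", dup),
         call. = FALSE)
  }
  bad <- setdiff(label, vocabulary)
  if (length(bad)) {
    stop(sprintf("label id %d outside the declared vocabulary", bad[1L]),
         call. = FALSE)
  }
  ord <- order(frame)
  structure(data.frame(frame = frame[ord], label = label[ord]),
            class = c("frame_labels", "data.frame"),
            vocabulary = as.integer(vocabulary))
}

#' Write a frame-label table
#'
#' @param labels A [frame_labels()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_labels <- function(labels, path) {
  stopifnot(inherits(labels, "frame_labels"))
  utils::write.csv(as.data.frame(labels), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a window feature table
#'
#' CSV with header `label,f0,...,f{F-1}`; feature values are written with
#' 17 significant digits so that the read/write round trip is exact for
#' doubles.
#'
#' @param fm A [feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  f <- fm$features
  con <- file(path, "w")
  on.exit(close(con))
  header <- paste(c("label", sprintf("f%d", seq_len(ncol(f)) - 1L)),
                  collapse = ",")
  writeLines(header, con)
  if (nrow(f) > 0L) {
    body <- vapply(seq_len(nrow(f)), function(i) {
      paste(c(fm$labels[i], sprintf("%.17g", f[i, ])), collapse = ",")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a window feature table
#'
#' Inverse of [write_feature_table()]. Ragged rows are rejected.
#'
#' @param path CSV path with header `label,f0,...,f{F-1}`.
#' @return A [feature_matrix()].
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty feature table file", call. = FALSE)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (header[1L] != "label") {
    stop("feature table header must start with 'label'", call. = FALSE)
  }
  width <- length(header) - 1L
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(feature_matrix(matrix(numeric(0), 0L, width), integer(0)))
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != width + 1L)) {
    bad <- which(lens != width + 1L)[1L]
    stop(sprintf("row %d has %d values, expected %d (ragged feature table)",
                 bad, lens[bad] - 1L, width), call. = FALSE)
  }
  labels <- as.integer(vapply(parts, `[`, character(1), 1L))
  feats <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                  nrow = length(labels), ncol = width, byrow = TRUE)
  feature_matrix(feats, labels)
}
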