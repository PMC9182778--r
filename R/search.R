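# Exhaustive search over window duration W and skeletons-per-window S,
# maximising cross-validated recall.

#' Search configuration
#'
#' @param W_grid Window durations in seconds (default `c(0.5, 1, 2)`).
#' @param T_max Maximum admissible window duration in seconds (upper
#'   bound on the grid; normally the shortest usable video duration).
#' @param model Classifier id used to score candidates (default `"knn"`,
#'   the fastest of the five with near-best accuracy).
#' @param rounds Evaluation rounds per candidate (default 10).
#' @param seed Base seed shared by every candidate's evaluation.
#' @return An object of class `search_config`.
#' @export
search_config <- function(W_grid = c(0.5, 1, 2), T_max = max(W_grid),
                          model = "knn", rounds = 10L, seed = 1L) {
  if (length(W_grid) == 0L) stop("window grid is empty", call. = FALSE)
  if (any(W_grid <= 0)) stop("window durations must be positive",
                             call. = FALSE)
  if (any(W_grid > T_max)) {
    stop(sprintf("window duration %g s exceeds the maximum admissible T = %g s",
                 max(W_grid), T_max), call. = FALSE)
  }
  model <- match.arg(model, MODEL_IDS)
  structure(list(W_grid = sort(W_grid), T_max = T_max, model = model,
                 rounds = as.integer(rounds), seed = as.integer(seed)),
            class = "search_config")
}

#' Enumerate (W, S) candidates
#'
#' For each window duration the admissible skeleton counts are
#' `S = 2 .. SWL` with `SWL = compute_swl(fps, W)`; candidates are
#' ordered by W then S. At 18 fps with the default grid this yields
#' 8 + 17 + 35 = 60 candidates.
#'
#' @param fps Frames per second.
#' @param config A [search_config()].
#' @return Data frame with columns `W`, `S`, `SWL`, `F`.
#' @export
enumerate_candidates <- function(fps, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  rows <- lapply(config$W_grid, function(W) {
    SWL <- compute_swl(fps, W)
    data.frame(W = W, S = 2:SWL, SWL = SWL,
               F = N_FRAME_FEATURES * (2:SWL))
  })
  do.call(rbind, rows)
}

#' Exhaustive search for the recall-maximising (W, S)
#'
#' For every candidate the tracks are windowized with that candidate's
#' spec, windows are pooled across videos, and the classifier is
#' evaluated with [run_protocol()]; the candidate table records the mean
#' and standard deviation of recall over rounds. The best candidate is
#' the argmax of mean recall, with ties broken toward smaller F (fewer
#' features) and then smaller W. Tracks shorter than a candidate's
#' window are skipped for that candidate with a warning.
#'
#' @param tracks List of [build_track()] results sharing one fps.
#' @param config A [search_config()].
#' @param task `"activity"` (macro recall, the default objective) or
#'   `"fall"` (positive-class recall).
#' @return An object of class `search_result`: list with `table` (one
#'   row per candidate: `W`, `S`, `F`, `n_windows`, `recall_mean`,
#'   `recall_sd`) and `best` (the winning row).
#' @export
exhaustive_search <- function(tracks, config = search_config(),
                              task = c("activity", "fall")) {
  task <- match.arg(task)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "pose_track")))
  fps <- unique(vapply(tracks, `[[`, integer(1), "fps"))
  if (length(fps) != 1L) stop("tracks have differing fps", call. = FALSE)
  cands <- enumerate_candidates(fps, config)
  if (nrow(cands) == 0L) stop("empty candidate set", call. = FALSE)
  res <- cands[, c("W", "S", "F")]
  res$n_windows <- NA_integer_
  res$recall_mean <- NA_real_
  res$recall_sd <- NA_real_
  # short tracks are assessed (and warned about) once per window duration
  usable_by_W <- lapply(config$W_grid, function(W) {
    SWL <- compute_swl(fps, W)
    usable <- vapply(tracks, function(tr) tr$n_frames >= SWL, logical(1))
    if (!all(usable)) {
      warning(sprintf("W=%g s: %d track(s) shorter than %d frames skipped",
                      W, sum(!usable), SWL), call. = FALSE)
    }
    usable
  })
  names(usable_by_W) <- as.character(config$W_grid)
  for (i in seq_len(nrow(cands))) {
    spec <- window_spec(fps, cands$W[i], cands$S[i])
    usable <- usable_by_W[[as.character(cands$W[i])]]
    fms <- lapply(tracks[usable], build_feature_matrix, spec = spec)
    fm <- bind_feature_matrices(fms)
    rep <- run_protocol(fm, model = config$model, task = task,
                        rounds = config$rounds, seed = config$seed)
    res$n_windows[i] <- fm$n_windows
    res$recall_mean[i] <- rep$mean[["recall"]]
    res$recall_sd[i] <- rep$sd[["recall"]]
  }
  ord <- order(-res$recall_mean, res$F, res$W)
  structure(list(table = res, best = res[ord[1L], ], fps = fps,
                 task = task, config = config),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("<search_result: %d candidates at %d fps, model %s, task '%s'>\n",
              nrow(x$table), x$fps, toupper(x$config$model), x$task))
  cat(sprintf("  best: W=%g s, S=%d, F=%d, recall %.2f%% +/- %.2f\n",
              b$W, b$S, b$F, b$recall_mean,
              if (is.na(b$recall_sd)) 0 else b$recall_sd))
  invisible(x)
}

#' Write a search result table as CSV
#'
#' Values are written with full precision so identical searches produce
#' byte-identical tables.
#'
#' @param result A [exhaustive_search()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_search_table <- function(result, path) {
  stopifnot(inherits(result, "search_result"))
  tb <- result$table
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("W,S,F,n_windows,recall_mean,recall_sd", con)
  writeLines(sprintf("%.17g,%d,%d,%d,%.17g,%.17g",
                     tb$W, tb$S, tb$F, tb$n_windows,
                     tb$recall_mean, tb$recall_sd), con)
  invisible(path)
}
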