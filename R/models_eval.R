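# Classifier training and evaluation: binary fall detection and
# 12-class activity recognition under repeated 70/30 splits, with the
# accuracy / precision / recall / specificity / F1 metric suite.

MODEL_IDS <- c("rf", "svm", "mlp", "knn", "adaboost")

#' Collapse activity ids to the binary fall task
#'
#' Ids 1--5 (the fall classes) become `"fall"`, ids 6--12 (daily
#' activities) become `"not_fall"`; `"fall"` is the positive class.
#'
#' @param labels Integer activity ids in 1--12.
#' @return Factor with levels `c("fall", "not_fall")`.
#' @export
collapse_to_binary <- function(labels) {
  labels <- as.integer(labels)
  bad <- setdiff(labels, activity_vocabulary())
  if (length(bad)) {
    stop(sprintf("label id %d outside the 1-12 vocabulary", bad[1L]),
         call. = FALSE)
  }
  factor(ifelse(labels %in% fall_ids(), "fall", "not_fall"),
         levels = c("fall", "not_fall"))
}

#' Confusion counts for a binary decision
#'
#' TP: positive detected as positive; FP: negative detected as positive;
#' TN: negative detected as negative; FN: positive detected as negative.
#'
#' @param truth True labels.
#' @param pred Predicted labels, same length.
#' @param positive The label value counted as the positive class.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(truth, pred, positive) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` lengths differ", call. = FALSE)
  }
  tpos <- truth == positive
  ppos <- pred == positive
  structure(list(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
                 TN = sum(!tpos & !ppos), FN = sum(tpos & !ppos)),
            class = "confusion_counts")
}

#' Metric suite from confusion counts
#'
#' Computes, as percentages:
#' accuracy = (TP+TN)/(TP+FP+TN+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), specificity = TN/(TN+FP), and
#' F1 = 2 * precision * recall / (precision + recall).
#' A ratio with zero denominator is reported as 0 with a warning
#' (in particular F1 is 0 when precision + recall = 0).
#'
#' @param counts A [confusion()] result.
#' @param quiet Suppress the zero-denominator warning (used internally
#'   for per-class macro averaging).
#' @return Named numeric vector `accuracy`, `precision`, `recall`,
#'   `specificity`, `f1`, all in `[0, 100]`.
#' @export
compute_metrics <- function(counts, quiet = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    n <- TP + FP + TN + FN
    if (n == 0) stop("all confusion counts are zero", call. = FALSE)
    ratio <- function(num, den, what) {
      if (den == 0) {
        if (!quiet) warning(sprintf("%s undefined (0/0); reported as 0", what),
                            call. = FALSE)
        return(0)
      }
      num / den
    }
    acc <- (TP + TN) / n
    prec <- ratio(TP, TP + FP, "precision")
    rec <- ratio(TP, TP + FN, "recall")
    spec <- ratio(TN, TN + FP, "specificity")
    f1 <- if (prec + rec == 0) {
      if (!quiet) warning("F1 undefined (precision + recall = 0); reported as 0",
                          call. = FALSE)
      0
    } else 2 * prec * rec / (prec + rec)
    100 * c(accuracy = acc, precision = prec, recall = rec,
            specificity = spec, f1 = f1)
  })
}

#' Macro-averaged metrics for a multi-class prediction
#'
#' Accuracy is the global fraction of correctly classified windows.
#' Precision, recall, specificity and F1 are the unweighted (macro)
#' means of the per-class one-vs-rest values from [compute_metrics()].
#' Classes absent from the truth are excluded from the macro mean with
#' a warning.
#'
#' @param truth Integer true labels.
#' @param pred Integer predicted labels, same length.
#' @param vocabulary Class ids considered; defaults to the ids present
#'   in the truth.
#' @return Named numeric vector as in [compute_metrics()].
#' @export
multiclass_metrics <- function(truth, pred, vocabulary = sort(unique(truth))) {
  if (length(truth) != length(pred)) {
    stop("`truth` and `pred` lengths differ", call. = FALSE)
  }
  if (length(truth) == 0L) stop("no observations", call. = FALSE)
  present <- vocabulary %in% truth
  if (any(!present)) {
    warning(sprintf("class%s %s absent from truth; excluded from macro averages",
                    if (sum(!present) > 1L) "es" else "",
                    paste(vocabulary[!present], collapse = ", ")),
            call. = FALSE)
  }
  per_class <- vapply(vocabulary[present], function(cl) {
    compute_metrics(confusion(truth, pred, positive = cl), quiet = TRUE)
  }, numeric(5))
  c(accuracy = 100 * mean(truth == pred),
    precision = mean(per_class["precision", ]),
    recall = mean(per_class["recall", ]),
    specificity = mean(per_class["specificity", ]),
    f1 = mean(per_class["f1", ]))
}

# --- classifiers -----------------------------------------------------------

#' Frozen classifier defaults
#'
#' Hyperparameters used by [run_protocol()] for each model id. These are
#' the backing libraries' defaults where the library has one (random
#' forest: 500 trees; SVM: RBF kernel, cost 1) and conventional values
#' where the library forces a choice (MLP: one hidden layer of 16 units,
#' weight decay 1e-4, 200 iterations; KNN: k = 5; AdaBoost: 50 SAMME
#' rounds of depth-1 stumps).
#'
#' @return Named list of per-model parameter lists.
#' @export
model_defaults <- function() {
  list(
    rf = list(ntree = 500L),
    svm = list(kernel = "radial", cost = 1),
    mlp = list(size = 16L, decay = 1e-4, maxit = 200L),
    knn = list(k = 5L),
    adaboost = list(n_rounds = 50L, maxdepth = 1L)
  )
}

fit_model <- function(model, x, y, seed) {
  model <- match.arg(model, MODEL_IDS)
  defs <- model_defaults()[[model]]
  set.seed(seed)
  fit <- switch(model,
    rf = randomForest::randomForest(x = x, y = y, ntree = defs$ntree),
    svm = e1071::svm(x = x, y = y, kernel = defs$kernel, cost = defs$cost),
    mlp = nnet::nnet(x = x, y = nnet::class.ind(y), size = defs$size,
                     decay = defs$decay, maxit = defs$maxit,
                     softmax = TRUE, MaxNWts = 200000L, trace = FALSE),
    knn = list(train_x = x, train_y = y, k = defs$k),
    adaboost = fit_adaboost(x, y, n_rounds = defs$n_rounds,
                            maxdepth = defs$maxdepth)
  )
  structure(list(model = model, fit = fit, levels = levels(y)),
            class = "skelwin_fit")
}

predict_model <- function(object, x) {
  stopifnot(inherits(object, "skelwin_fit"))
  lv <- object$levels
  out <- switch(object$model,
    rf = as.character(predict(object$fit, x)),
    svm = as.character(predict(object$fit, x)),
    mlp = {
      p <- predict(object$fit, x)
      colnames(p)[max.col(p, ties.method = "first")]
    },
    knn = as.character(class::knn(object$fit$train_x, x,
                                  object$fit$train_y, k = object$fit$k)),
    adaboost = predict_adaboost(object$fit, x)
  )
  factor(out, levels = lv)
}

# SAMME multi-class AdaBoost over rpart stumps. Weighted stumps are the
# base learner; alpha includes the log(K-1) SAMME correction so the
# algorithm stays valid for K > 2.
fit_adaboost <- function(x, y, n_rounds = 50L, maxdepth = 1L) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  n <- nrow(df)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w,
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = maxdepth, cp = -1, minsplit = 2L,
                            xval = 0L))
    pred <- predict(stump, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    if (err >= 1 - 1 / K) break       # no better than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break           # perfect stump: one vote suffices
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(stumps) == 0L) {
    # degenerate data; fall back to a single unweighted stump
    stumps <- list(rpart::rpart(.y ~ ., data = df, method = "class",
                                control = rpart::rpart.control(
                                  maxdepth = maxdepth, xval = 0L)))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y),
       feature_names = colnames(x))
}

predict_adaboost <- function(fit, x) {
  df <- data.frame(x, check.names = FALSE)
  votes <- matrix(0, nrow(df), length(fit$levels),
                  dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], df, type = "class")
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + fit$alphas[m]
  }
  fit$levels[max.col(votes, ties.method = "first")]
}

# --- evaluation protocol ---------------------------------------------------

#' Train and evaluate a classifier under repeated 70/30 splits
#'
#' Implements the evaluation protocol: `rounds` repeated random
#' train/test partitions of the pooled window set (70% training by
#' default), fitting the chosen model on each training split and scoring
#' the held-out windows. For the `"fall"` task labels are first collapsed
#' with [collapse_to_binary()] and metrics come from the binary confusion
#' counts with `"fall"` positive; for the `"activity"` task metrics are
#' macro-averaged over classes via [multiclass_metrics()].
#'
#' Splits are drawn at window level, so overlapping windows from one
#' video can appear on both sides of a split — this mirrors the protocol
#' the headline results use; see the package vignette for caveats.
#'
#' @param fm A [feature_matrix()].
#' @param model One of `"rf"`, `"svm"`, `"mlp"`, `"knn"`, `"adaboost"`.
#' @param task `"fall"` (binary) or `"activity"` (multi-class).
#' @param rounds Number of repeated splits (default 10).
#' @param train_fraction Fraction of windows used for training
#'   (default 0.70).
#' @param seed Base seed; round `r` uses `seed + r` for its split and
#'   model fit, so identical seeds reproduce the report exactly.
#' @param standardize Centre/scale features using training-split
#'   statistics before fitting (off by default).
#' @param split_by `"window"` (default) draws splits over pooled
#'   windows, matching the benchmark protocol even though overlapping
#'   windows leak between train and test; `"video"` assigns whole
#'   videos to one side, giving honest generalization estimates
#'   (requires the matrix to carry video provenance, as matrices built
#'   by [build_feature_matrix()] do).
#' @return An object of class `metrics_report`: list with `model`,
#'   `task`, `rounds`, `per_round` (rounds x 5 metric matrix), `mean`,
#'   `sd`, and `confusions` (per-round confusion tables).
#' @export
run_protocol <- function(fm, model = "rf", task = c("fall", "activity"),
                         rounds = 10L, train_fraction = 0.7, seed = 1L,
                         standardize = FALSE,
                         split_by = c("window", "video")) {
  stopifnot(inherits(fm, "feature_matrix"))
  task <- match.arg(task)
  split_by <- match.arg(split_by)
  if (split_by == "video" && anyNA(fm$video)) {
    stop("video-level splits need a matrix with video provenance",
         call. = FALSE)
  }
  model <- match.arg(model, MODEL_IDS)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  if (rounds < 1L) stop("`rounds` must be >= 1", call. = FALSE)
  y <- if (task == "fall") collapse_to_binary(fm$labels)
       else factor(fm$labels)
  if (nlevels(droplevels(y)) < 2L) {
    stop("evaluation needs at least two classes present", call. = FALSE)
  }
  y <- droplevels(y)
  x <- fm$features
  colnames(x) <- sprintf("f%d", seq_len(ncol(x)) - 1L)
  n <- nrow(x)
  n_train <- floor(train_fraction * n)
  per_round <- matrix(NA_real_, rounds, 5L,
                      dimnames = list(NULL, c("accuracy", "precision",
                                              "recall", "specificity", "f1")))
  confusions <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    attempt <- 0L
    repeat {
      set.seed(seed + r + attempt * 100003L)
      train_idx <- if (split_by == "window") {
        sample.int(n, n_train)
      } else {
        vids <- unique(fm$video)
        train_vids <- sample(vids, max(1L, floor(train_fraction *
                                                   length(vids))))
        which(fm$video %in% train_vids)
      }
      if (length(train_idx) < n &&
          nlevels(droplevels(y[train_idx])) == nlevels(y)) break
      attempt <- attempt + 1L
      warning(sprintf("round %d: training split missed a class; redrawn", r),
              call. = FALSE)
      if (attempt > 100L) stop("cannot draw a training split with all classes",
                               call. = FALSE)
    }
    train_x <- x[train_idx, , drop = FALSE]
    test_x <- x[-train_idx, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(train_x)
      sdv <- apply(train_x, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      train_x <- scale(train_x, mu, sdv)
      test_x <- scale(test_x, mu, sdv)
    }
    fit <- fit_model(model, train_x, y[train_idx], seed = seed + r)
    pred <- predict_model(fit, test_x)
    truth <- y[-train_idx]
    if (task == "fall") {
      cc <- confusion(truth, pred, positive = "fall")
      per_round[r, ] <- compute_metrics(cc, quiet = TRUE)
      confusions[[r]] <- cc
    } else {
      per_round[r, ] <- suppressWarnings(
        multiclass_metrics(as.integer(as.character(truth)),
                           as.integer(as.character(pred))))
      confusions[[r]] <- table(truth = truth, pred = pred)
    }
  }
  structure(list(model = model, task = task, rounds = rounds,
                 train_fraction = train_fraction, seed = seed,
                 split_by = split_by,
                 per_round = per_round,
                 mean = colMeans(per_round),
                 sd = apply(per_round, 2L, stats::sd),
                 confusions = confusions),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report: %s, task '%s', %d round%s of %.0f/%.0f splits>\n",
              toupper(x$model), x$task, x$rounds,
              if (x$rounds == 1L) "" else "s",
              100 * x$train_fraction, 100 * (1 - x$train_fraction)))
  m <- x$mean
  s <- x$sd
  for (nm in names(m)) {
    cat(sprintf("  %-12s %6.2f%% +/- %.2f\n", nm, m[[nm]],
                if (is.na(s[[nm]])) 0 else s[[nm]]))
  }
  invisible(x)
}
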