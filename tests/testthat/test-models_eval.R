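test_that("binary collapse maps fall ids to the positive class", {
  expect_equal(as.character(collapse_to_binary(c(1, 3, 5))),
               rep("fall", 3))
  expect_equal(as.character(collapse_to_binary(c(6, 11, 12))),
               rep("not_fall", 3))
  expect_equal(as.character(collapse_to_binary(c(2, 7))),
               c("fall", "not_fall"))
  expect_error(collapse_to_binary(c(1, 13)), "outside")
})

test_that("confusion counts enumerate the four outcomes", {
  cc <- confusion(c("+", "+", "-", "-"), c("+", "-", "-", "+"), "+")
  expect_equal(unclass(cc)[c("TP", "FN", "TN", "FP")],
               list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  cc2 <- confusion(c("+", "-", "+"), c("+", "-", "+"), "+")
  expect_equal(cc2$FP + cc2$FN, 0L)
  cc3 <- confusion(rep("-", 5), rep("+", 5), "+")
  expect_equal(cc3$TP, 0L)
  expect_equal(cc3$FP, 5L)
  expect_error(confusion(c("+", "-"), c("+"), "+"), "lengths differ")
})

test_that("the metric formulas evaluate exactly on hand-checked counts", {
  # 4425 fall windows of which 5 missed: recall 99.89% to 2 dp
  m <- compute_metrics(confusion(
    rep(c("fall", "not"), c(4425, 1000)),
    rep(c("fall", "not", "not"), c(4420, 5, 1000)), "fall"))
  expect_equal(m[["recall"]], 100 * 4420 / 4425, tolerance = 1e-12)
  expect_equal(round(m[["recall"]], 2), 99.89)

  perfect <- structure(list(TP = 50L, FP = 0L, TN = 50L, FN = 0L),
                       class = "confusion_counts")
  expect_equal(unname(compute_metrics(perfect)), rep(100, 5))

  hand <- structure(list(TP = 8L, FP = 2L, TN = 85L, FN = 5L),
                    class = "confusion_counts")
  m <- compute_metrics(hand)
  expect_equal(round(m[["precision"]], 2), 80.00)
  expect_equal(round(m[["recall"]], 2), 61.54)
  expect_equal(round(m[["accuracy"]], 2), 93.00)
  expect_equal(round(m[["specificity"]], 2), 97.70)
  expect_equal(round(m[["f1"]], 2), 69.57)
})

test_that("zero denominators are reported as 0 with a warning", {
  cc <- structure(list(TP = 0L, FP = 0L, TN = 10L, FN = 0L),
                  class = "confusion_counts")
  m <- suppressWarnings(compute_metrics(cc))
  w <- capture_warnings(compute_metrics(cc))
  expect_length(w, 3)    # precision, recall and F1 are all 0/0 here
  expect_true(all(grepl("undefined", w)))
  expect_equal(m[["precision"]], 0)
  expect_equal(m[["recall"]], 0)
  expect_equal(m[["f1"]], 0)
  zero <- structure(list(TP = 0L, FP = 0L, TN = 0L, FN = 0L),
                    class = "confusion_counts")
  expect_error(compute_metrics(zero), "all-zero|zero")
})

test_that("metrics agree with independent arithmetic on random tables", {
  set.seed(40)
  for (i in 1:1000) {
    counts <- as.list(sample(0:30, 4, replace = TRUE))
    names(counts) <- c("TP", "FP", "TN", "FN")
    if (sum(unlist(counts)) == 0) counts$TN <- 1L
    cc <- structure(counts, class = "confusion_counts")
    expect_equal(compute_metrics(cc, quiet = TRUE),
                 oracle_metrics(counts$TP, counts$FP, counts$TN, counts$FN),
                 tolerance = 1e-12)
  }
})

test_that("macro multiclass metrics match the enumeration example", {
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c(1, 1, 2, 2, 3, 2)
  m <- multiclass_metrics(truth, pred)
  expect_equal(m[["accuracy"]], 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(m[["recall"]], mean(c(100, 100, 50)), tolerance = 1e-12)

  perf <- multiclass_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(perf), rep(100, 5))

  expect_warning(one <- multiclass_metrics(c(2, 2), c(2, 2),
                                           vocabulary = c(2, 3)),
                 "absent")
  expect_equal(one[["accuracy"]], 100)
})

test_that("multiclass accuracy is invariant under label permutation", {
  set.seed(41)
  truth <- sample(1:5, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, sample(1:5, 200, replace = TRUE))
  base <- multiclass_metrics(truth, pred)
  for (i in 1:5) {
    perm <- sample(1:5)
    m <- multiclass_metrics(perm[truth], perm[pred])
    expect_equal(m[["accuracy"]], base[["accuracy"]], tolerance = 1e-12)
    expect_equal(m[["recall"]], base[["recall"]], tolerance = 1e-12)
  }
})

# two well-separated Gaussian clusters: class 1 (fall) around +10,
# class 6 (not fall) around -10, 51 features
separable_fm <- function(n = 400, seed = 42) {
  set.seed(seed)
  y <- rep(c(1L, 6L), each = n / 2)
  x <- matrix(rnorm(n * 51), n, 51) + ifelse(y == 1L, 10, -10)
  fm_of(x, y)
}

test_that("a separable dataset is classified perfectly every round", {
  fm <- separable_fm()
  rep <- run_protocol(fm, model = "knn", task = "fall", rounds = 5, seed = 1)
  expect_true(all(rep$per_round[, "accuracy"] == 100))
  expect_equal(unname(rep$mean["recall"]), 100)
})

test_that("shuffled labels drop accuracy to the chance level", {
  fm <- separable_fm()
  set.seed(43)
  fm_null <- fm_of(fm$features, sample(fm$labels))   # break the link
  rep <- run_protocol(fm_null, model = "knn", task = "fall",
                      rounds = 10, seed = 2)
  # balanced classes: chance accuracy 50%, binomial error over 1200
  # held-out predictions leaves a generous 45-55% band
  expect_gt(unname(rep$mean["accuracy"]), 42)
  expect_lt(unname(rep$mean["accuracy"]), 58)
})

test_that("identical seeds reproduce the report exactly", {
  fm <- separable_fm(n = 120, seed = 44)
  for (model in c("rf", "knn")) {
    a <- run_protocol(fm, model = model, task = "fall", rounds = 2, seed = 5)
    b <- run_protocol(fm, model = model, task = "fall", rounds = 2, seed = 5)
    expect_identical(a$per_round, b$per_round)
    expect_identical(a$mean, b$mean)
  }
})

test_that("all five classifiers run and beat chance on separable data", {
  fm <- separable_fm(n = 120, seed = 45)
  for (model in c("rf", "svm", "mlp", "knn", "adaboost")) {
    rep <- run_protocol(fm, model = model, task = "fall",
                        rounds = 2, seed = 3)
    expect_gt(unname(rep$mean["accuracy"]), 90)
  }
})

test_that("the multiclass protocol handles more than two classes", {
  set.seed(46)
  y <- rep(c(1L, 6L, 11L), each = 60)
  x <- matrix(rnorm(180 * 51), 180, 51) +
    c(-10, 0, 10)[match(y, c(1L, 6L, 11L))]
  rep <- run_protocol(fm_of(x, y), model = "knn", task = "activity",
                      rounds = 3, seed = 4)
  expect_equal(unname(rep$mean["recall"]), 100)
  expect_true(all(dim(rep$confusions[[1]]) == c(3, 3)))
})

test_that("video-level splits keep whole videos on one side", {
  trks <- lapply(1:6, function(v) {
    set.seed(100 + v)
    tr <- random_track(30, fps = 18,
                       labels = rep(if (v %% 2) 1L else 6L, 30),
                       video_id = sprintf("v%d", v))
    tr$features <- tr$features + if (v %% 2) 5 else -5
    tr
  })
  fm <- bind_feature_matrices(lapply(trks, build_feature_matrix,
                                     spec = window_spec(18, 0.5, 2)))
  expect_equal(sort(unique(fm$video)), sprintf("v%d", 1:6))
  rep <- run_protocol(fm, model = "knn", task = "fall", rounds = 3,
                      seed = 2, split_by = "video")
  expect_gt(unname(rep$mean["accuracy"]), 95)
  expect_identical(rep$split_by, "video")
  # provenance-free matrices cannot be split by video
  bare <- fm_of(fm$features, fm$labels)
  expect_error(run_protocol(bare, model = "knn", task = "fall",
                            split_by = "video"),
               "provenance")
})

test_that("degenerate single-class input is rejected", {
  fm <- fm_of(matrix(rnorm(20 * 51), 20, 51), rep(6L, 20))
  expect_error(run_protocol(fm, model = "knn", task = "fall"),
               "two classes")
})
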