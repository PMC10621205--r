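# Small labeled feature tables built directly (fast) plus synthetic
# acceleration data where the full path matters.

fake_labeled <- function(counts, seed = 1, sep = 5) {
  withr::with_seed(seed, {
    labs <- rep(names(counts), times = counts)
    n <- length(labs)
    centers <- sep * (match(labs, behavior_classes()) - 1)
    # class signal present in every feature column (non-overlapping
    # supports at large sep), plus unit noise
    df <- as.data.frame(matrix(rnorm(n * 44), ncol = 44) + centers)
    names(df) <- feature_names("all")
    df$odba <- abs(df$odba)
    df$label <- labs
    df
  })
}

test_that("balancing subsamples every class to the rarest count", {
  df <- fake_labeled(c(motionless = 100, travel = 80, foraging = 30, grooming = 45))
  bal <- balance_classes(df, seed = 1)
  expect_equal(nrow(bal), 120L)
  expect_true(all(table(bal$label) == 30))
  # deterministic under the seed
  bal2 <- balance_classes(df, seed = 1)
  expect_identical(rownames(bal), rownames(bal2))
  bal3 <- balance_classes(df, seed = 2)
  expect_false(identical(rownames(bal), rownames(bal3)))
  # already balanced input returned intact
  expect_identical(balance_classes(bal, seed = 9), bal)
  # a missing class is an error listing counts
  df2 <- df[df$label != "grooming", ]
  expect_error(balance_classes(df2, seed = 1), "grooming=0")
})

test_that("the stratified split partitions exactly with per-class halves", {
  df <- fake_labeled(c(motionless = 30, travel = 30, foraging = 30, grooming = 30))
  sp <- split_train_test(df, seed = 3)
  expect_equal(nrow(sp$train), 60L)
  expect_equal(nrow(sp$test), 60L)
  expect_true(all(table(sp$train$label) == 15))
  expect_true(all(table(sp$test$label) == 15))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0L)
  expect_setequal(c(rownames(sp$train), rownames(sp$test)), rownames(df))
  sp2 <- split_train_test(df, seed = 3)
  expect_identical(rownames(sp$train), rownames(sp2$train))
  expect_error(split_train_test(df, fraction = 1), "strictly between")
})

test_that("perfectly separated classes are classified without error", {
  df <- fake_labeled(
    c(motionless = 40, travel = 40, foraging = 40, grooming = 40),
    sep = 50
  )
  sp <- split_train_test(df, seed = 1)
  for (alg in c("linear_svm", "decision_tree", "random_forest")) {
    rep <- evaluate_model(model_spec(alg, "all", 6, seed = 1), sp$train, sp$test)
    expect_equal(rep$metrics$overall_accuracy, 1.0)
    expect_true(all(rep$confusion[row(rep$confusion) != col(rep$confusion)] == 0))
  }
})

test_that("permuted labels give chance-level accuracy", {
  df <- fake_labeled(
    c(motionless = 60, travel = 60, foraging = 60, grooming = 60),
    sep = 50
  )
  withr::with_seed(5, df$label <- sample(df$label))
  sp <- split_train_test(df, seed = 5)
  rep <- evaluate_model(model_spec("random_forest", "all", 6, seed = 5), sp$train, sp$test)
  n <- sum(rep$confusion)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(rep$metrics$overall_accuracy - 0.25), 3 * se)
})

test_that("confusion-matrix metrics follow the defining formulas", {
  # one class with TP = 9, FP = 1, FN = 3 inside a 4-class matrix
  cm <- matrix(0, 4, 4, dimnames = list(behavior_classes(), behavior_classes()))
  cm["travel", "travel"] <- 9
  cm["motionless", "travel"] <- 1 # FP for travel
  cm["travel", "foraging"] <- 3 # FN for travel
  cm["motionless", "motionless"] <- 10
  cm["foraging", "foraging"] <- 8
  cm["grooming", "grooming"] <- 12
  m <- metrics_from_confusion(cm)
  trv <- m$per_class[m$per_class$class == "travel", ]
  expect_equal(trv$precision, 0.90)
  expect_equal(trv$recall, 0.75)
  expect_equal(trv$accuracy, (9 + (sum(cm) - 9 - 1 - 3)) / sum(cm))
  expect_equal(m$overall_accuracy, sum(diag(cm)) / sum(cm))
})

test_that("stored metrics always equal metrics recomputed from the stored matrix", {
  df <- fake_labeled(
    c(motionless = 40, travel = 40, foraging = 40, grooming = 40),
    sep = 2
  )
  sp <- split_train_test(df, seed = 2)
  for (alg in c("linear_svm", "decision_tree", "random_forest")) {
    rep <- evaluate_model(model_spec(alg, "all", 6, seed = 2), sp$train, sp$test)
    re <- metrics_from_confusion(rep$confusion)
    expect_equal(re$overall_accuracy, rep$metrics$overall_accuracy, tolerance = 1e-12)
    expect_equal(re$macro_precision, rep$metrics$macro_precision, tolerance = 1e-12)
    expect_equal(re$macro_recall, rep$metrics$macro_recall, tolerance = 1e-12)
  }
})

test_that("SVM standardization derives from the training half only", {
  df <- fake_labeled(
    c(motionless = 40, travel = 40, foraging = 40, grooming = 40),
    sep = 3
  )
  sp <- split_train_test(df, seed = 4)
  rep <- evaluate_model(model_spec("linear_svm", "all", 6, seed = 4), sp$train, sp$test)
  Xtr <- as.matrix(sp$train[, feature_names("all")])
  expect_equal(rep$model$scaling$center, colMeans(Xtr), tolerance = 1e-12)
  expect_equal(
    rep$model$train_checksum,
    sum(Xtr) + nrow(sp$train)
  )
})

test_that("non-finite feature columns are rejected by name", {
  df <- fake_labeled(c(motionless = 10, travel = 10, foraging = 10, grooming = 10))
  df$odba[3] <- NA
  expect_error(balance_classes(df, seed = 1), "odba")
})

test_that("model selection ranks by the documented score with deterministic ties", {
  tabs <- list(
    "2" = fake_labeled(
      c(motionless = 40, travel = 40, foraging = 40, grooming = 40),
      seed = 6, sep = 0.5
    ),
    "6" = fake_labeled(
      c(motionless = 40, travel = 40, foraging = 40, grooming = 40),
      seed = 7, sep = 6
    )
  )
  sel <- model_selection(tabs,
    algorithms = c("random_forest", "decision_tree"),
    feature_sets = "all", seed = 8
  )
  lb <- sel$leaderboard
  expect_equal(
    lb$score,
    (lb$macro_accuracy + lb$macro_precision + lb$macro_recall) / 3
  )
  expect_true(all(diff(lb$score) <= 1e-12))
  # the best report matches the leaderboard head
  expect_equal(sel$best$spec$algorithm, lb$algorithm[1])
  expect_equal(sel$best$spec$window_s, lb$window_s[1])
  # a one-spec grid returns that spec
  sel1 <- model_selection(tabs["6"], algorithms = "decision_tree",
                          feature_sets = "all", seed = 8)
  expect_equal(nrow(sel1$leaderboard), 1L)
  expect_equal(sel1$best$spec$algorithm, "decision_tree")
  # identical grids rank identically across runs (tie-break determinism)
  selA <- model_selection(tabs, algorithms = c("random_forest", "decision_tree"),
                          feature_sets = "all", seed = 8)
  expect_identical(sel$leaderboard, selA$leaderboard)
})

test_that("a motionless-only trace is annotated almost entirely motionless", {
  td <- simulate_training_data(windows_per_class = 80, window_s = 6, seed = 21)
  w <- label_windows(segment(td$trace, 6), td$annotations)
  ft <- feature_table(w)
  bal <- balance_classes(ft, seed = 21)
  sp <- split_train_test(bal, seed = 21)
  rep <- evaluate_model(model_spec("random_forest", "all", 6, seed = 21), sp$train, sp$test)

  sched <- data.frame(
    behavior = "motionless",
    start = utc("2021-06-02 03:00:00"),
    end = utc("2021-06-02 03:30:00")
  )
  tr <- synthesize_accel(sched, seed = 22, deployment_id = "quiet")
  ann <- annotate_deployment(tr, rep$model)
  expect_equal(nrow(ann), 300L) # 30 min / 6 s
  expect_gte(mean(ann$behavior == "motionless"), 0.99)
  # deterministic
  ann2 <- annotate_deployment(tr, rep$model)
  expect_identical(ann, ann2)

  # a trace of exactly one window gives one prediction
  tr1 <- synthesize_accel(
    data.frame(
      behavior = "motionless",
      start = utc("2021-06-02 03:00:00"),
      end = utc("2021-06-02 03:00:06")
    ),
    seed = 23
  )
  expect_equal(nrow(annotate_deployment(tr1, rep$model)), 1L)
  # shorter than one window: empty with warning
  tr0 <- synthesize_accel(
    data.frame(
      behavior = "motionless",
      start = utc("2021-06-02 03:00:00"),
      end = utc("2021-06-02 03:00:03")
    ),
    seed = 24
  )
  expect_warning(out <- annotate_deployment(tr0, rep$model), "shorter")
  expect_equal(nrow(out), 0L)
})

test_that("leave-one-individual-out holds out exactly that animal's windows", {
  df1 <- fake_labeled(
    c(motionless = 30, travel = 30, foraging = 30, grooming = 30),
    seed = 31, sep = 8
  )
  df1$deployment_id <- "id01"
  df2 <- fake_labeled(
    c(motionless = 25, travel = 25, foraging = 25, grooming = 25),
    seed = 32, sep = 8
  )
  df2$deployment_id <- "id02"
  tabs <- list("6" = rbind(df1, df2))
  sel <- model_selection(tabs,
    algorithms = "decision_tree", feature_sets = "all",
    seed = 33, holdout_individual = "id02"
  )
  rep <- sel$best
  expect_equal(sum(rep$test_sizes), 100L) # all of id02
  expect_equal(sum(rep$train_sizes), 120L) # id01, balanced
  expect_error(
    model_selection(tabs,
      algorithms = "decision_tree", feature_sets = "all",
      seed = 33, holdout_individual = "nobody"
    ),
    "not present"
  )
})
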