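# Class balancing, train/test evaluation of the three classifiers
# (linear SVM, decision tree, random forest) across feature sets and
# window sizes, best-model selection and whole-deployment annotation.

.ALGORITHMS <- c("linear_svm", "decision_tree", "random_forest")

#' Model specification
#'
#' @param algorithm One of `"linear_svm"`, `"decision_tree"`,
#'   `"random_forest"`.
#' @param feature_set `"all"` (44 features) or `"reduced"` (7 features).
#' @param window_s Window size in seconds.
#' @param seed Integer seed controlling algorithm randomness.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(algorithm, feature_set = c("all", "reduced"),
                       window_s, seed = 1) {
  algorithm <- match.arg(algorithm, .ALGORITHMS)
  feature_set <- match.arg(feature_set)
  stopifnot(window_s > 0)
  structure(
    list(
      algorithm = algorithm, feature_set = feature_set,
      window_s = window_s, seed = as.integer(seed)
    ),
    class = "model_spec"
  )
}

# A labeled feature data.frame: feature columns + a `label` column.
.check_labeled <- function(df) {
  stopifnot(is.data.frame(df), "label" %in% names(df))
  df <- df[!is.na(df$label), , drop = FALSE]
  if (nrow(df) == 0L) stop("no labeled windows")
  feats <- intersect(feature_names("all"), names(df))
  bad <- feats[vapply(df[feats], function(v) any(!is.finite(v)), logical(1))]
  if (length(bad) > 0L) {
    stop("non-finite feature values in column(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Balance classes by subsampling to the rarest class
#'
#' Each behavioral class is subsampled without replacement to the count
#' of the rarest class; deterministic under the seed. An already balanced
#' input is returned with its membership intact.
#'
#' @param df Labeled feature data.frame (`label` column).
#' @param seed Integer seed.
#' @return Balanced data.frame (row order: original order within class
#'   blocks).
#' @export
balance_classes <- function(df, seed = 1) {
  df <- .check_labeled(df)
  counts <- table(factor(df$label, levels = behavior_classes()))
  if (any(counts == 0L)) {
    stop(
      "every class must be present before balancing; counts: ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
    )
  }
  m <- min(counts)
  if (m < 2L) stop("need at least 2 windows in the rarest class")
  if (all(counts == m)) {
    return(df)
  }
  .run_seeded(seed, {
    keep <- unlist(lapply(behavior_classes(), function(cl) {
      rows <- which(df$label == cl)
      if (length(rows) == m) rows else sort(sample(rows, m))
    }))
    df[keep, , drop = FALSE]
  })
}

#' Stratified random train/test split
#'
#' Splits the balanced window set into train and test halves, stratified
#' by class so all classes appear on both sides even at small n. The
#' partition is exact: no overlap, union equals the input.
#'
#' @param df Labeled feature data.frame.
#' @param fraction Training fraction (default 0.5); each class
#'   contributes `floor(fraction * n_class)` training rows.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(df, fraction = 0.5, seed = 1) {
  df <- .check_labeled(df)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1 (both halves nonempty)")
  }
  counts <- table(df$label)
  if (any(counts < 2L)) stop("need at least 2 windows per class to split")
  .run_seeded(seed, {
    tr_rows <- unlist(lapply(names(counts), function(cl) {
      rows <- which(df$label == cl)
      sort(sample(rows, floor(fraction * length(rows))))
    }))
    list(
      train = df[tr_rows, , drop = FALSE],
      test = df[-tr_rows, , drop = FALSE]
    )
  })
}

# Fit one classifier on a labeled feature data.frame.
.fit_classifier <- function(spec, train) {
  feats <- feature_names(spec$feature_set)
  X <- as.matrix(train[, feats, drop = FALSE])
  y <- factor(train$label, levels = behavior_classes())
  scaling <- NULL
  if (spec$algorithm == "linear_svm") {
    # standardize with train-only statistics; zero-variance columns are
    # centered but not scaled
    mu <- colMeans(X)
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0] <- 1
    scaling <- list(center = mu, scale = sd)
  }
  fit <- .run_seeded(spec$seed, switch(spec$algorithm,
    linear_svm = {
      Xs <- scale(X, center = scaling$center, scale = scaling$scale)
      e1071::svm(Xs, y, kernel = "linear", scale = FALSE)
    },
    decision_tree = {
      d <- data.frame(X, label = y, check.names = FALSE)
      rpart::rpart(label ~ ., data = d, method = "class")
    },
    random_forest = {
      randomForest::randomForest(X, y)
    }
  ))
  structure(
    list(
      spec = spec, fit = fit, scaling = scaling, features = feats,
      classes = behavior_classes(),
      train_checksum = sum(X) + as.numeric(length(y))
    ),
    class = "behavior_model"
  )
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf(
    "<behavior_model> %s, %s features, %g s windows\n",
    x$spec$algorithm, x$spec$feature_set, x$spec$window_s
  ))
  invisible(x)
}

#' Predict behaviors for a feature table
#'
#' Runs under a seed derived from the model's stored seed: the random
#' forest breaks exact vote ties at random, and an unseeded prediction
#' would make repeated annotation runs differ by a handful of windows.
#'
#' @param object A `behavior_model`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.behavior_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  pred <- .run_seeded(object$spec$seed + 271L, switch(object$spec$algorithm,
    linear_svm = {
      Xs <- scale(X, center = object$scaling$center, scale = object$scaling$scale)
      stats::predict(object$fit, Xs)
    },
    decision_tree = {
      d <- data.frame(X, check.names = FALSE)
      cls <- stats::predict(object$fit, d, type = "class")
      cls
    },
    random_forest = stats::predict(object$fit, X)
  ))
  factor(as.character(pred), levels = object$classes)
}

#' Metrics from a confusion matrix
#'
#' One-vs-rest per-class accuracy, precision (`TP / (TP + FP)`), recall
#' (`TP / (TP + FN)`), plus overall accuracy and unweighted macro
#' averages. Undefined ratios (empty denominators) are reported as 0.
#'
#' @param cm Square confusion matrix of counts, rows = true class,
#'   columns = predicted class.
#' @return List: `per_class` data.frame, `overall_accuracy`,
#'   `macro_accuracy`, `macro_precision`, `macro_recall`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  per_class <- data.frame(
    class = rownames(cm),
    accuracy = (tp + tn) / total,
    precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    n_true = rowSums(cm)
  )
  rownames(per_class) <- NULL
  list(
    per_class = per_class,
    overall_accuracy = sum(tp) / total,
    macro_accuracy = mean(per_class$accuracy),
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall)
  )
}

#' Train on the train half and evaluate on the test half
#'
#' Fits the specified algorithm (standardizing features with train-only
#' statistics for the SVM), predicts the test half and fills the 4x4
#' confusion matrix and all derived metrics.
#'
#' @param spec A [model_spec()].
#' @param train,test Labeled feature data.frames (disjoint).
#' @return List of class `model_report`: `spec`, `model`, `confusion`
#'   (rows = true class), `metrics`, `train_sizes`, `test_sizes`.
#' @export
evaluate_model <- function(spec, train, test) {
  train <- .check_labeled(train)
  test <- .check_labeled(test)
  model <- .fit_classifier(spec, train)
  pred <- predict(model, test)
  truth <- factor(test$label, levels = behavior_classes())
  cm <- table(true = truth, predicted = pred)
  cm <- unclass(as.matrix(cm))
  structure(
    list(
      spec = spec, model = model, confusion = cm,
      metrics = metrics_from_confusion(cm),
      train_sizes = table(train$label), test_sizes = table(test$label)
    ),
    class = "model_report"
  )
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf(
    "<model_report> %s/%s/%gs: overall accuracy %.3f\n",
    x$spec$algorithm, x$spec$feature_set, x$spec$window_s,
    x$metrics$overall_accuracy
  ))
  print(x$confusion)
  invisible(x)
}

# selection score: unweighted mean of macro accuracy, precision, recall
.selection_score <- function(metrics) {
  mean(c(metrics$macro_accuracy, metrics$macro_precision, metrics$macro_recall))
}

#' Evaluate a model grid and select the best classifier
#'
#' For every window size, the pooled labeled windows are balanced (to the
#' rarest class) and split 50/50 stratified by class, with the same seeds
#' across specs so all algorithms see identical data. Every
#' (algorithm, feature set, window size) combination is evaluated; specs
#' are ranked by the mean of macro accuracy, macro precision and macro
#' recall, with ties broken by macro recall, then smaller window, then
#' algorithm name.
#'
#' @param labeled_tables Named list: one labeled feature data.frame per
#'   window size, names = window size in seconds (as from
#'   [feature_table()] after [label_windows()], pooled over deployments).
#' @param algorithms Character vector of algorithms to try.
#' @param feature_sets Character vector of feature sets to try.
#' @param seed Integer seed (balancing, splitting and algorithms).
#' @param fraction Training fraction for the split.
#' @param holdout_individual Optional deployment/individual id: instead of
#'   the pooled random split, that individual's windows form the test set
#'   and the remaining individuals (balanced) form the training set
#'   (leave-one-individual-out mode; off by default, the pooled split is
#'   the standard protocol).
#' @return List of class `model_selection`: `leaderboard` (one row per
#'   spec, ranked), `reports` (all `model_report`s), `best` (top report).
#' @export
model_selection <- function(labeled_tables,
                            algorithms = .ALGORITHMS,
                            feature_sets = c("all", "reduced"),
                            seed = 1, fraction = 0.5,
                            holdout_individual = NULL) {
  stopifnot(length(labeled_tables) > 0L, !is.null(names(labeled_tables)))
  algorithms <- match.arg(algorithms, .ALGORITHMS, several.ok = TRUE)
  reports <- list()
  rows <- list()
  for (w in names(labeled_tables)) {
    df <- .check_labeled(labeled_tables[[w]])
    if (is.null(holdout_individual)) {
      bal <- balance_classes(df, seed = seed)
      sp <- split_train_test(bal, fraction = fraction, seed = seed)
    } else {
      if (!"deployment_id" %in% names(df) ||
        !holdout_individual %in% df$deployment_id) {
        stop("holdout individual not present: ", holdout_individual)
      }
      held <- df$deployment_id == holdout_individual
      sp <- list(
        train = balance_classes(df[!held, , drop = FALSE], seed = seed),
        test = df[held, , drop = FALSE]
      )
    }
    for (alg in algorithms) {
      for (fsname in feature_sets) {
        spec <- model_spec(alg, fsname, as.numeric(w), seed = seed)
        rep <- evaluate_model(spec, sp$train, sp$test)
        key <- paste(alg, fsname, w, sep = "|")
        reports[[key]] <- rep
        m <- rep$metrics
        rows[[key]] <- data.frame(
          algorithm = alg, feature_set = fsname, window_s = as.numeric(w),
          overall_accuracy = m$overall_accuracy,
          macro_accuracy = m$macro_accuracy,
          macro_precision = m$macro_precision,
          macro_recall = m$macro_recall,
          score = .selection_score(m),
          n_train = nrow(sp$train), n_test = nrow(sp$test)
        )
      }
    }
  }
  lb <- do.call(rbind, rows)
  o <- order(-lb$score, -lb$macro_recall, lb$window_s, lb$algorithm)
  lb <- lb[o, , drop = FALSE]
  rownames(lb) <- NULL
  best_key <- paste(lb$algorithm[1], lb$feature_set[1], lb$window_s[1], sep = "|")
  structure(
    list(leaderboard = lb, reports = reports, best = reports[[best_key]]),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> leaderboard (top 5):\n")
  print(utils::head(x$leaderboard, 5), digits = 3)
  invisible(x)
}

#' Annotate a whole deployment with the selected model
#'
#' Segments the trace at the model's window size, computes features and
#' predicts a behavior for every complete window, yielding a step-function
#' behavior time series.
#'
#' @param trace An [accel_trace()].
#' @param model A `behavior_model` (e.g. `selection$best$model`).
#' @return data.frame: `deployment_id`, `start`, `end`, `behavior` (one
#'   row per window). A trace shorter than one window yields zero rows
#'   with a warning.
#' @export
annotate_deployment <- function(trace, model) {
  stopifnot(inherits(trace, "accel_trace"), inherits(model, "behavior_model"))
  w <- model$spec$window_s
  if (nrow(trace$xyz) < round(w * trace$fs)) {
    warning("trace shorter than one window; empty annotation")
    return(data.frame(
      deployment_id = character(), start = as.POSIXct(character(), tz = "UTC"),
      end = as.POSIXct(character(), tz = "UTC"), behavior = character()
    ))
  }
  wins <- segment(trace, w)
  feats <- as.data.frame(compute_features(wins, model$spec$feature_set))
  pred <- predict(model, feats)
  data.frame(
    deployment_id = trace$deployment_id,
    start = wins$starts,
    end = wins$starts + w,
    behavior = as.character(pred)
  )
}
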