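.model_kinds <- c("logistic", "naive-bayes", "decision-tree",
                  "random-forest", "gradient-boosted-trees")

default_hyper <- function(kind) {
  switch(kind,
    "logistic" = list(),
    "naive-bayes" = list(laplace = 0),
    "decision-tree" = list(cp = 1e-4, minsplit = 20L, maxdepth = 30L),
    "random-forest" = list(num_trees = 100L, mtry = NULL),
    "gradient-boosted-trees" = list(nrounds = 100L, max_depth = 6L,
                                    eta = 0.3),
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

#' Fit a screening-uptake classifier
#'
#' One interface over the five classifier families used for uptake
#' prediction: logistic regression, Gaussian naive Bayes, a decision tree,
#' a random forest and gradient-boosted trees. All models consume the
#' numeric encoded feature matrix; survey/SMOTE weights are passed to the
#' fitting routine where the backend supports per-record weights
#' (logistic, tree, forest, boosting) and applied by frequency replication
#' for naive Bayes. The `feature_set` argument switches between the base
#' model (socioeconomic rank factors only) and the final model (all
#' variables including access covariates).
#'
#' @param kind One of `"logistic"`, `"naive-bayes"`, `"decision-tree"`,
#'   `"random-forest"`, `"gradient-boosted-trees"`.
#' @param data An `"encoded_matrix"` with both outcome classes present.
#' @param hyper Named list of hyperparameters; unspecified entries fall
#'   back to fixed defaults (100 trees for ensembles, near-unpruned tree,
#'   unpenalised logistic).
#' @param seed Integer seed controlling any randomness in fitting.
#' @param feature_set `"all"` (final model), `"base"` (rank factors only),
#'   or a character vector of variable names.
#' @param use_weights Pass record weights to the fit (default TRUE).
#' @return Object of class `"uptake_model"` with a `predict()` method
#'   returning event probabilities.
#' @examples
#' d <- encode_features(generate_survey(dgp_config(400, seed = 2,
#'   intercept = 0, coef = c(wealth_quintile = 0.4))))
#' m <- fit_model("decision-tree", d, seed = 1)
#' summary(predict(m, d))
#' @export
fit_model <- function(kind, data, hyper = list(), seed = 1L,
                      feature_set = "all", use_weights = TRUE) {
  kind <- match.arg(kind, .model_kinds)
  stopifnot(inherits(data, "encoded_matrix"))
  if (!identical(feature_set, "all")) {
    vars <- if (identical(feature_set, "base")) {
      names(Filter(function(m) isTRUE(m$base), data$encoding_map))
    } else feature_set
    data <- subset_features(data, vars)
  }
  if (length(unique(data$y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  hp <- utils::modifyList(default_hyper(kind), hyper)
  X <- data$X
  y <- data$y
  w <- if (use_weights) data$w else rep(1, length(y))

  set.seed(seed)
  fit <- switch(
    kind,
    "logistic" = {
      suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y, weights = w,
                       family = stats::binomial())
      )["coefficients"]
    },
    "naive-bayes" = {
      dat <- as.data.frame(X)
      if (use_weights && diff(range(w)) > 1e-12) {
        reps <- pmax(1L, as.integer(round(w)))
        dat <- dat[rep(seq_len(nrow(dat)), reps), , drop = FALSE]
        yy <- rep(y, reps)
      } else yy <- y
      e1071::naiveBayes(dat, factor(yy, levels = c(0, 1)),
                        laplace = hp$laplace)
    },
    "decision-tree" = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), X,
                       check.names = FALSE)
      rpart::rpart(
        .y ~ ., data = df, weights = w, method = "class",
        control = rpart::rpart.control(cp = hp$cp, minsplit = hp$minsplit,
                                       maxdepth = hp$maxdepth, xval = 0)
      )
    },
    "random-forest" = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), X,
                       check.names = FALSE)
      ranger::ranger(
        .y ~ ., data = df, num.trees = hp$num_trees, mtry = hp$mtry,
        probability = TRUE, case.weights = w, seed = seed,
        num.threads = 1L, respect.unordered.factors = TRUE
      )
    },
    "gradient-boosted-trees" = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0
      )
    }
  )
  structure(
    list(kind = kind, fit = fit, hyper = hp, seed = as.integer(seed),
         feature_names = colnames(X), encoding_map = data$encoding_map),
    class = "uptake_model"
  )
}

#' Predicted event probabilities
#'
#' @param object An `"uptake_model"`.
#' @param newdata An `"encoded_matrix"` or numeric matrix whose columns
#'   match the training features.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.uptake_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "encoded_matrix")) newdata$X else
    as.matrix(newdata)
  if (!identical(colnames(X), object$feature_names)) {
    if (!all(object$feature_names %in% colnames(X)))
      stop("newdata lacks training feature columns", call. = FALSE)
    X <- X[, object$feature_names, drop = FALSE]
  }
  p <- switch(
    object$kind,
    "logistic" = {
      beta <- object$fit$coefficients
      beta[is.na(beta)] <- 0
      as.numeric(stats::plogis(cbind(1, X) %*% beta))
    },
    "naive-bayes" = {
      pr <- stats::predict(object$fit, as.data.frame(X), type = "raw")
      as.numeric(pr[, "1"])
    },
    "decision-tree" = {
      pr <- stats::predict(object$fit,
                           data.frame(X, check.names = FALSE),
                           type = "prob")
      as.numeric(pr[, "1"])
    },
    "random-forest" = {
      pr <- stats::predict(object$fit,
                           data = data.frame(X, check.names = FALSE),
                           num.threads = 1L)$predictions
      as.numeric(pr[, "1"])
    },
    "gradient-boosted-trees" =
      as.numeric(stats::predict(object$fit, xgboost::xgb.DMatrix(X)))
  )
  pmin(pmax(p, 0), 1)
}

#' @export
print.uptake_model <- function(x, ...) {
  cat(sprintf("Uptake classifier (%s), %d features, seed %d\n",
              x$kind, length(x$feature_names), x$seed))
  invisible(x)
}

#' @export
summary.uptake_model <- function(object, ...) {
  print(object)
  cat("Variables:",
      paste(names(object$encoding_map), collapse = ", "), "\n")
  invisible(object)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form: the probability that a random positive record
#' receives a higher score than a random negative one, with ties counted
#' one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return Scalar AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUROC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted classifier
#'
#' Computes the five evaluation metrics at a classification threshold:
#' accuracy, precision, recall, F1 (threshold-based, from the confusion
#' counts) and AUROC (threshold-free, from the scores). Metrics whose
#' denominator is zero (for example precision with no predicted positives)
#' are reported as `NA` and flagged in `undefined`, never as silent zeros.
#'
#' @param model An `"uptake_model"`.
#' @param data Labeled `"encoded_matrix"`.
#' @param threshold Probability threshold for the positive call
#'   (default 0.5).
#' @return Object of class `"metrics_report"`: accuracy, precision,
#'   recall, f1, auroc, threshold, confusion counts `tp/fp/tn/fn`, and
#'   `undefined` (names of undefined metrics).
#' @export
evaluate <- function(model, data, threshold = 0.5) {
  stopifnot(inherits(model, "uptake_model"),
            inherits(data, "encoded_matrix"))
  scores <- predict(model, data)
  y <- as.integer(data$y)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else {
      undefined <- c(undefined, "f1"); NA_real_
    }
  structure(
    list(accuracy = (tp + tn) / length(y), precision = precision,
         recall = recall, f1 = f1, auroc = auroc(scores, y),
         threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         undefined = undefined),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf(
    "accuracy %.*f | precision %.*f | recall %.*f | F1 %.*f | AUROC %.*f (threshold %.2f)\n",
    digits, x$accuracy, digits, x$precision, digits, x$recall,
    digits, x$f1, digits, x$auroc, x$threshold))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# Collect a metrics_report into a one-row data frame.
.metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy, precision = m$precision,
             recall = m$recall, f1 = m$f1, auroc = m$auroc)
}

#' Cross-validated evaluation
#'
#' Fits and evaluates one classifier kind over the folds of a split plan
#' (training portion only): for each fold the model is fitted on the other
#' folds and scored on the held-out fold; per-fold metrics and the pooled
#' out-of-fold AUROC are returned.
#'
#' @param data An `"encoded_matrix"`.
#' @param kind Model kind (see [fit_model()]).
#' @param plan A `"split_plan"` from [make_splits()].
#' @param hyper,seed,feature_set,use_weights Passed to [fit_model()].
#' @return List with `fold_metrics` (data frame, one row per fold) and
#'   `pooled_auroc` (AUROC of pooled out-of-fold scores).
#' @export
cross_validate <- function(data, kind, plan, hyper = list(), seed = 1L,
                           feature_set = "all", use_weights = TRUE) {
  stopifnot(inherits(plan, "split_plan"))
  rows <- list()
  oof_scores <- rep(NA_real_, length(plan$train_idx))
  for (f in seq_len(plan$k)) {
    tr <- plan$train_idx[plan$folds != f]
    te <- plan$train_idx[plan$folds == f]
    model <- fit_model(kind, slice_records(data, tr), hyper = hyper,
                       seed = seed + f, feature_set = feature_set,
                       use_weights = use_weights)
    test_slice <- slice_records(data, te)
    if (!identical(feature_set, "all")) {
      vars <- if (identical(feature_set, "base"))
        names(Filter(function(m) isTRUE(m$base), data$encoding_map))
      else feature_set
      test_slice <- subset_features(test_slice, vars)
    }
    rows[[f]] <- .metrics_row(evaluate(model, test_slice))
    oof_scores[plan$folds == f] <- predict(model, test_slice)
  }
  list(
    fold_metrics = do.call(rbind, rows),
    pooled_auroc = auroc(oof_scores, data$y[plan$train_idx])
  )
}

#' Stability analysis over repeated train/test splits
#'
#' Re-splits the data `n_splits` times with consecutive seeds; for each
#' split, fits each requested classifier kind on the training portion and
#' evaluates it on the held-out test portion. Reports the full per-split
#' log and, per kind and metric, the mean and standard deviation across
#' splits. Fit failures inside a split are recorded and that entry is
#' dropped from the summary.
#'
#' @param data An `"encoded_matrix"`.
#' @param kinds Character vector of model kinds.
#' @param n_splits Number of repeated splits (at least 2; default 10).
#' @param seed Base seed; split `s` uses `seed + s - 1`.
#' @param ratio Train fraction per split.
#' @param hyper Optional named list of per-kind hyperparameter lists.
#' @param use_weights Passed to [fit_model()].
#' @return Object of class `"stability_report"`: `log` (one row per split
#'   and kind), `summary` (mean and SD per kind and metric), `failures`.
#' @export
stability_analysis <- function(data, kinds, n_splits = 10L, seed = 1L,
                               ratio = 0.8, hyper = list(),
                               use_weights = TRUE) {
  if (n_splits < 2L) stop("'n_splits' must be at least 2", call. = FALSE)
  log_rows <- list()
  failures <- list()
  for (s in seq_len(n_splits)) {
    plan <- make_splits(data, ratio = ratio, k = 2L, seed = seed + s - 1L)
    train <- slice_records(data, plan$train_idx)
    test <- slice_records(data, plan$test_idx)
    for (kind in kinds) {
      res <- tryCatch({
        model <- fit_model(kind, train, hyper = if (kind %in% names(hyper))
          hyper[[kind]] else list(), seed = seed + s - 1L,
          use_weights = use_weights)
        cbind(data.frame(split = s, model = kind),
              .metrics_row(evaluate(model, test)))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(split = s, model = kind,
                     message = conditionMessage(res))
      } else {
        log_rows[[length(log_rows) + 1L]] <- res
      }
    }
  }
  log <- do.call(rbind, log_rows)
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auroc")
  summ <- do.call(rbind, lapply(split(log, log$model), function(d) {
    data.frame(
      model = d$model[1],
      metric = metric_cols,
      mean = vapply(metric_cols, function(m) mean(d[[m]]), 1),
      sd = vapply(metric_cols, function(m) stats::sd(d[[m]]), 1),
      row.names = NULL
    )
  }))
  structure(
    list(log = log, summary = summ,
         failures = if (length(failures)) do.call(rbind, failures) else NULL,
         n_splits = as.integer(n_splits), seed = as.integer(seed)),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, digits = 3, ...) {
  cat(sprintf("Stability analysis over %d splits\n", x$n_splits))
  s <- x$summary
  s$mean <- round(s$mean, digits)
  s$sd <- round(s$sd, digits)
  print(s, row.names = FALSE)
  if (!is.null(x$failures))
    cat(nrow(x$failures), "fit failure(s) recorded\n")
  invisible(x)
}
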