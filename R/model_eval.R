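#' Series-level train/test split with grouped folds
#'
#' Splits series ids 75-25 into train and hold-out test sets at the
#' series level (a series appears exclusively in train or test) and
#' assigns every training series to one of `k` cross-validation folds,
#' balanced within one series.
#'
#' @param series_ids character vector of series identifiers.
#' @param test_fraction fraction of series held out.
#' @param k number of folds over the training series.
#' @param seed integer seed; the plan is deterministic given it.
#' @return list of class `split_plan` with `train`, `test`, `fold`
#'   (named integer vector over training series) and `seed`.
#' @export
split_series <- function(series_ids, test_fraction = 0.25, k = 5L, seed = 1L) {
  ids <- unique(as.character(series_ids))
  n <- length(ids)
  if (n < k + 1L) stop("too few series for ", k, "-fold grouped CV")
  set.seed(seed)
  n_test <- round(n * test_fraction)
  test <- sort(sample(ids, n_test))
  train <- setdiff(ids, test)
  shuffled <- sample(train)
  fold <- stats::setNames(rep_len(seq_len(k), length(train)), shuffled)
  fold <- fold[order(names(fold))]
  structure(list(train = sort(train), test = test, fold = fold,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "split_plan")
}

# instances -> (feature matrix, label, series) in a fixed column order
instance_matrix <- function(instances, feature_cols = NULL) {
  dt <- data.table::as.data.table(instances)
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(dt), c("series_id", "group", "day_offset", "label"))
  x <- as.matrix(dt[, feature_cols, with = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(dt$label), series = as.character(dt$series_id),
       feature_cols = feature_cols)
}

# Thin wrapper over the compiled booster.
gbt_fit <- function(x, y, n_trees = 200L, max_depth = 4L, learning_rate = 0.1,
                    subsample = 1, colsample = 1, min_child_weight = 1,
                    lambda = 1, valid = NULL, early_stopping = 10L, seed = 1L) {
  if (length(unique(y)) < 2L) stop("single-class training data")
  fit <- .gbt_fit_cpp(x, y, as.integer(n_trees), as.integer(max_depth),
                      learning_rate, subsample, colsample, min_child_weight,
                      lambda,
                      if (is.null(valid)) NULL else valid$x,
                      if (is.null(valid)) NULL else valid$y,
                      as.integer(early_stopping), as.integer(seed))
  structure(list(booster = fit, feature_cols = colnames(x),
                 params = list(n_trees = n_trees, max_depth = max_depth,
                               learning_rate = learning_rate,
                               subsample = subsample, colsample = colsample,
                               min_child_weight = min_child_weight,
                               lambda = lambda),
                 n_trees_used = fit$n_trees),
            class = "gbt_model")
}

#' Predict exacerbation risk with a fitted boosted-tree model
#'
#' @param object a model from [tune_and_train()] / `gbt_fit`.
#' @param newdata `prediction_instances` table or a numeric feature
#'   matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of risk scores (probabilities).
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata
       else instance_matrix(newdata, object$feature_cols)$x
  margin <- .gbt_predict_cpp(object$booster, x)
  1 / (1 + exp(-margin))
}

default_search_space <- function() {
  list(max_depth = c(2L, 6L), learning_rate = c(0.02, 0.3),
       n_trees = c(50L, 250L), subsample = c(0.5, 1), colsample = c(0.5, 1))
}

#' Tune and train the boosted-tree risk model
#'
#' Budgeted hyperparameter search with grouped cross-validation: each
#' candidate configuration is scored by the mean out-of-fold average
#' precision over the plan's series-grouped folds (the held-out fold
#' also drives early stopping of the tree count); the best
#' configuration is then refitted on the full training set with the
#' tree count the folds settled on. The search is a seeded random
#' search over `space` (log-uniform learning rate).
#'
#' @param instances `prediction_instances` for the training series (any
#'   rows from test series are dropped via `plan`).
#' @param plan a [split_series()] plan.
#' @param budget number of configurations evaluated.
#' @param seed integer seed for the search.
#' @param space named list of parameter ranges (see
#'   `default_search_space`).
#' @param early_stopping early-stopping patience (trees) on the
#'   out-of-fold loss; 0 disables.
#' @return list of class `tuned_model`: `model` (a `gbt_model`),
#'   `best_params`, `trials` (one row per configuration with its mean
#'   out-of-fold average precision).
#' @export
tune_and_train <- function(instances, plan, budget = 30L, seed = 1L,
                           space = default_search_space(),
                           early_stopping = 10L) {
  stopifnot(inherits(plan, "split_plan"), budget >= 1)
  dt <- data.table::as.data.table(instances)[series_id %in% plan$train]
  if (length(unique(dt$label)) < 2L) stop("single-class training data")
  im <- instance_matrix(dt)
  fold_of <- plan$fold[im$series]

  set.seed(seed)
  trials <- vector("list", budget)
  for (t in seq_len(budget)) {
    par <- list(
      max_depth = sample(space$max_depth[1]:space$max_depth[2], 1),
      learning_rate = exp(runif(1, log(space$learning_rate[1]),
                                log(space$learning_rate[2]))),
      n_trees = sample(space$n_trees[1]:space$n_trees[2], 1),
      subsample = runif(1, space$subsample[1], space$subsample[2]),
      colsample = runif(1, space$colsample[1], space$colsample[2]))
    ap_f <- n_used <- numeric(plan$k)
    for (f in seq_len(plan$k)) {
      tr <- fold_of != f
      va <- !tr
      if (length(unique(im$y[tr])) < 2L || length(unique(im$y[va])) < 2L) {
        ap_f[f] <- NA_real_; next
      }
      fit <- gbt_fit(im$x[tr, , drop = FALSE], im$y[tr],
                     n_trees = par$n_trees, max_depth = par$max_depth,
                     learning_rate = par$learning_rate,
                     subsample = par$subsample, colsample = par$colsample,
                     valid = list(x = im$x[va, , drop = FALSE], y = im$y[va]),
                     early_stopping = early_stopping,
                     seed = seed + t)
      sc <- predict(fit, im$x[va, , drop = FALSE])
      ap_f[f] <- average_precision(im$y[va], sc)
      n_used[f] <- fit$n_trees_used
    }
    trials[[t]] <- data.table::data.table(
      trial = t, max_depth = par$max_depth, learning_rate = par$learning_rate,
      n_trees = par$n_trees, subsample = par$subsample, colsample = par$colsample,
      mean_oof_ap = mean(ap_f, na.rm = TRUE),
      n_trees_used = round(mean(n_used[n_used > 0])))
  }
  trials <- data.table::rbindlist(trials)
  best <- trials[which.max(mean_oof_ap)]
  final_trees <- max(10L, as.integer(best$n_trees_used))
  model <- gbt_fit(im$x, im$y, n_trees = final_trees,
                   max_depth = best$max_depth,
                   learning_rate = best$learning_rate,
                   subsample = best$subsample, colsample = best$colsample,
                   seed = seed)
  structure(list(model = model,
                 best_params = as.list(best[, .(max_depth, learning_rate,
                                                n_trees = final_trees,
                                                subsample, colsample)]),
                 trials = trials, seed = seed),
            class = "tuned_model")
}

#' @export
predict.tuned_model <- function(object, newdata, ...) predict(object$model, newdata)

#' Area under the ROC curve
#'
#' Equals the probability that a randomly chosen positive instance
#' outranks a randomly chosen negative one, with ties counted one half
#' (Mann-Whitney formulation via mean ranks).
#'
#' @param labels binary labels (0/1).
#' @param scores numeric risk scores.
#' @return value in \[0, 1\].
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (area under the precision-recall curve)
#'
#' Sum over score thresholds (descending) of precision at the threshold
#' times the recall increment; tied scores are treated as a single
#' threshold.
#'
#' @inheritParams auroc
#' @return value in \[0, 1\].
#' @export
average_precision <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  P <- sum(labels == 1)
  if (P == 0) stop("at least one positive required")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]; sc <- scores[o]
  # last index of each tied-score block
  block_end <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[block_end]
  n_at <- block_end
  prec <- tp / n_at
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Stratified evaluation with bootstrap confidence intervals
#'
#' Scores the test instances once with the fitted model, then reports
#' AUROC and average precision per engagement group with percentile
#' bootstrap 95% confidence intervals obtained by resampling whole
#' series (never single instances, so within-series correlation is
#' respected). A group whose test set lacks one of the classes is
#' reported as unevaluable rather than dropped.
#'
#' @param model fitted model (`tuned_model`, `gbt_model` or
#'   `logistic_baseline`).
#' @param instances test `prediction_instances` with a `group` column.
#' @param boot_reps bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return `data.table` of class `evaluation_report`: one row per group
#'   with point metrics, CI bounds, series/instance counts and positive
#'   fraction.
#' @export
evaluate_by_group <- function(model, instances, boot_reps = 1000L, seed = 1L,
                              conf = 0.95) {
  dt <- data.table::as.data.table(instances)
  stopifnot("group" %in% names(dt))
  sc <- predict(model, dt)
  dt <- dt[, .(series_id, group, label)]
  dt[, score := sc]
  alpha <- (1 - conf) / 2
  set.seed(seed)
  rows <- lapply(split(seq_len(nrow(dt)), dt$group), function(idx) {
    g <- dt[idx]
    gname <- as.character(g$group[1])
    n_series <- length(unique(g$series_id))
    base <- data.table::data.table(
      group = gname, n_series = n_series, n_instances = nrow(g),
      positive_fraction = mean(g$label == 1))
    if (length(unique(g$label)) < 2L)
      return(cbind(base, auroc = NA_real_, auroc_lo = NA_real_, auroc_hi = NA_real_,
                   average_precision = NA_real_, ap_lo = NA_real_, ap_hi = NA_real_,
                   unevaluable = TRUE))
    a <- auroc(g$label, g$score)
    ap <- average_precision(g$label, g$score)
    by_series <- split(seq_len(nrow(g)), g$series_id)
    sids <- names(by_series)
    boot_a <- boot_ap <- rep(NA_real_, boot_reps)
    for (b in seq_len(boot_reps)) {
      take <- sample(sids, n_series, replace = TRUE)
      ridx <- unlist(by_series[take], use.names = FALSE)
      lb <- g$label[ridx]
      if (length(unique(lb)) < 2L) next
      boot_a[b] <- auroc(lb, g$score[ridx])
      boot_ap[b] <- average_precision(lb, g$score[ridx])
    }
    cbind(base,
          auroc = a,
          auroc_lo = stats::quantile(boot_a, alpha, na.rm = TRUE, names = FALSE),
          auroc_hi = stats::quantile(boot_a, 1 - alpha, na.rm = TRUE, names = FALSE),
          average_precision = ap,
          ap_lo = stats::quantile(boot_ap, alpha, na.rm = TRUE, names = FALSE),
          ap_hi = stats::quantile(boot_ap, 1 - alpha, na.rm = TRUE, names = FALSE),
          unevaluable = FALSE)
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class", c("evaluation_report", class(out)))
  out[]
}

#' Logistic-regression baseline
#'
#' Linear comparator run through the same evaluation pathway as the
#' boosted-tree model. Missing feature values are median-imputed with
#' medians computed on the training split only (linear models cannot
#' represent absence natively).
#'
#' @param instances training `prediction_instances`.
#' @param plan a [split_series()] plan; only `plan$train` series are
#'   used.
#' @return list of class `logistic_baseline` with coefficients, the
#'   training medians and the feature columns.
#' @export
train_logistic_baseline <- function(instances, plan) {
  dt <- data.table::as.data.table(instances)[series_id %in% plan$train]
  if (length(unique(dt$label)) < 2L) stop("single-class training data")
  im <- instance_matrix(dt)
  med <- apply(im$x, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  x <- im$x
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, x), im$y,
                        family = stats::binomial())
  structure(list(coef = fit$coefficients, medians = med,
                 feature_cols = im$feature_cols),
            class = "logistic_baseline")
}

#' @export
predict.logistic_baseline <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata
       else instance_matrix(newdata, object$feature_cols)$x
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- object$medians[j]
  beta <- object$coef
  beta[is.na(beta)] <- 0
  eta <- drop(cbind(1, x) %*% beta)
  1 / (1 + exp(-eta))
}
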