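#' Default hyperparameter grid for the boosted-tree classifier
#'
#' Small grid spanning number of boosting rounds, learning rate, tree
#' depth and per-tree column subsampling. It contains the
#' configuration that wins on the morphology problem (100 estimators,
#' depth 2, learning rate 0.1, one fifth of the columns per tree).
#'
#' @return data.frame with columns `nrounds`, `max_depth`, `eta`,
#'   `colsample_bytree`.
#' @export
gbt_default_grid <- function() {
  expand.grid(
    nrounds = c(50L, 100L),
    max_depth = c(2L, 3L),
    eta = c(0.1, 0.3),
    colsample_bytree = c(0.2, 1),
    KEEP.OUT.ATTRS = FALSE
  )
}

# stratified fold ids: within each class, round-robin after shuffling
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k && length(idx) < 1L) {
      gp_stop("a class has no observations; stratified folding impossible",
              "gp_fold_error")
    }
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

gbt_train <- function(x, y, pars, seed = 1L) {
  xgboost::xgboost(
    x, factor(y, levels = c(0L, 1L)),
    objective = "binary:logistic",
    nrounds = pars$nrounds, max_depth = pars$max_depth,
    learning_rate = pars$eta,
    colsample_bytree = pars$colsample_bytree,
    nthreads = 1L, seed = seed, verbosity = 0
  )
}

gbt_accuracy <- function(model, x, y) {
  mean((predict(model, x) > 0.5) == y)
}

#' Nested cross-validated gradient boosted trees
#'
#' Binary classification with gradient boosted trees (logistic loss,
#' depth-limited trees, per-tree column subsampling, via xgboost).
#' Hyperparameters are selected by an inner k-fold cross-validation
#' within each outer training fold (accuracy criterion; ties broken by
#' fewer rounds, then shallower trees), and performance is estimated
#' on the untouched outer test folds, giving an unbiased estimate.
#' Gain importance (total loss reduction attributed to each feature's
#' splits) is averaged over the outer-fold models after per-model
#' normalisation.
#'
#' @param table data.frame with the label column and feature columns.
#' @param label_column name of the binary label column.
#' @param features feature columns (default all 25 present).
#' @param grid hyperparameter data.frame (default
#'   [gbt_default_grid()]).
#' @param outer,inner fold counts of the nested cross-validation.
#' @param seed integer seed (stratified folds and xgboost are seeded
#'   from it).
#' @return list of class `gbt_cv_report`: `fold_metrics` (accuracy /
#'   precision / recall per outer fold), `accuracy`, `accuracy_sd`,
#'   `precision`, `recall`, `selected` (chosen hyperparameters per
#'   fold), `importance` (named numeric, sums to 1), `levels`.
#' @export
gbt_nested_cv <- function(table, label_column = "genotype", features = NULL,
                          grid = gbt_default_grid(), outer = 5L, inner = 5L,
                          seed = 1L) {
  gp_assert(label_column %in% names(table), "label column not found")
  y_fac <- droplevels(as.factor(table[[label_column]]))
  gp_assert(nlevels(y_fac) == 2L, "label must be binary")
  gp_assert(nrow(grid) >= 1L, "hyperparameter grid is empty")
  features <- features %||% intersect(morpho_feature_names(), names(table))
  gp_assert(length(features) >= 1L, "no feature columns found")
  x <- as.matrix(table[, features, drop = FALSE])
  y <- as.integer(y_fac) - 1L

  # parsimony ordering for tie-breaks: fewer rounds, then lower depth
  grid <- grid[order(grid$nrounds, grid$max_depth), , drop = FALSE]

  with_seed(seed, {
    next_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)
    ofolds <- stratified_folds(y, outer)
    fold_metrics <- data.frame()
    selected <- data.frame()
    importances <- list()
    for (of in seq_len(outer)) {
      tr <- which(ofolds != of); te <- which(ofolds == of)
      if (length(unique(y[te])) < 1L || length(tr) < 2L) {
        gp_stop("outer fold with insufficient data", "gp_fold_error")
      }
      best <- NULL
      if (nrow(grid) == 1L) {
        best <- grid[1, , drop = FALSE]
      } else {
        ifolds <- stratified_folds(y[tr], inner)
        scores <- vapply(seq_len(nrow(grid)), function(gi) {
          accs <- vapply(seq_len(inner), function(inf) {
            itr <- tr[ifolds != inf]; ite <- tr[ifolds == inf]
            if (length(ite) == 0L) return(NA_real_)
            mod <- gbt_train(x[itr, , drop = FALSE], y[itr], grid[gi, ], seed = next_seed())
            gbt_accuracy(mod, x[ite, , drop = FALSE], y[ite])
          }, numeric(1))
          mean(accs, na.rm = TRUE)
        }, numeric(1))
        best <- grid[which.max(scores), , drop = FALSE] # first max = most parsimonious
      }
      mod <- gbt_train(x[tr, , drop = FALSE], y[tr], best, seed = next_seed())
      pred <- predict(mod, x[te, , drop = FALSE]) > 0.5
      truth <- y[te] == 1L
      acc <- mean(pred == truth)
      prec <- if (sum(pred) > 0) sum(pred & truth) / sum(pred) else NA_real_
      rec <- if (sum(truth) > 0) sum(pred & truth) / sum(truth) else NA_real_
      fold_metrics <- rbind(fold_metrics, data.frame(
        fold = of, accuracy = acc, precision = prec, recall = rec
      ))
      selected <- rbind(selected, cbind(fold = of, best))
      imp <- xgboost::xgb.importance(model = mod)
      v <- setNames(rep(0, length(features)), features)
      if (!is.null(imp) && nrow(imp) > 0) v[imp$Feature] <- imp$Gain
      importances[[of]] <- v / max(sum(v), .Machine$double.eps)
    }
    importance <- Reduce(`+`, importances) / length(importances)
    importance <- importance / sum(importance)
    structure(
      list(
        fold_metrics = fold_metrics,
        accuracy = mean(fold_metrics$accuracy),
        accuracy_sd = sd(fold_metrics$accuracy),
        precision = mean(fold_metrics$precision, na.rm = TRUE),
        recall = mean(fold_metrics$recall, na.rm = TRUE),
        selected = selected,
        importance = importance,
        levels = levels(y_fac)
      ),
      class = "gbt_cv_report"
    )
  })
}

#' @export
print.gbt_cv_report <- function(x, ...) {
  cat(sprintf(
    "<gbt_cv_report> accuracy %.3f +- %.3f, precision %.3f, recall %.3f (%d outer folds)\n",
    x$accuracy, x$accuracy_sd, x$precision, x$recall, nrow(x$fold_metrics)
  ))
  top <- head(sort(x$importance, decreasing = TRUE), 4)
  cat("  top gain:", paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Ranked gain importance from a nested-CV report
#'
#' @param report a [gbt_nested_cv()] result.
#' @return data.frame `feature`, `gain` (normalised to sum 1), sorted
#'   decreasing.
#' @export
gain_importance <- function(report) {
  gp_assert(inherits(report, "gbt_cv_report"), "report must be a gbt_cv_report")
  imp <- sort(report$importance, decreasing = TRUE)
  data.frame(feature = names(imp), gain = as.numeric(imp),
             stringsAsFactors = FALSE)
}
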