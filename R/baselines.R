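# Random-forest and RBF support-vector regression baselines with
# grid-searched hyperparameters, scored by cross-validated Spearman.

#' Baseline hyperparameter grids
#'
#' Default grids: random-forest trees M in 1..99 and mtry in 1..29; SVM
#' cost C in {0.01, 0.1, 0.5, 1, 5, 10, 15, 20} and RBF gamma in
#' 2^-6..2^6.  Pass smaller grids for quick runs.
#'
#' @param rf_trees,rf_mtry,svm_cost,svm_gamma Numeric grids.
#' @return List of the four grids.
#' @export
baseline_grids <- function(rf_trees = 1:99, rf_mtry = 1:29,
                           svm_cost = c(0.01, 0.1, 0.5, 1, 5, 10, 15, 20),
                           svm_gamma = 2^(-6:6)) {
  if (!all(lengths(list(rf_trees, rf_mtry, svm_cost, svm_gamma)) > 0)) {
    stop("all grids must be non-empty")
  }
  list(rf_trees = rf_trees, rf_mtry = rf_mtry,
       svm_cost = svm_cost, svm_gamma = svm_gamma)
}

cv_model_spearman <- function(x, y, fold_assign, fit_fun, predict_fun) {
  scores <- vapply(sort(unique(fold_assign)), function(f) {
    test <- fold_assign == f
    fit <- fit_fun(x[!test, , drop = FALSE], y[!test])
    spearman_gamma(y[test], predict_fun(fit, x[test, , drop = FALSE]))
  }, numeric(1))
  mean(scores)
}

#' Grid-searched RFR and SVMR baselines
#'
#' Cross-validates a random-forest regressor over (trees, mtry) and an
#' RBF support-vector regressor over (cost, gamma), selecting each
#' model's best configuration by mean held-out Spearman on folds shared
#' with the PLSR evaluation.
#'
#' @param x Feature matrix. @param y Response vector.
#' @param grids Grids from [baseline_grids()].
#' @param folds,seed Fold geometry.
#' @param fold_assign Optional precomputed assignment.
#' @return List with elements `rfr` and `svmr`, each holding `best`
#'   (config + score) and `grid` (all scored configs), plus the shared
#'   `fold_assign`.
#' @export
fit_baselines <- function(x, y, grids = baseline_grids(), folds = 5,
                          seed = 1, fold_assign = NULL) {
  if (!requireNamespace("randomForest", quietly = TRUE) ||
      !requireNamespace("e1071", quietly = TRUE)) {
    stop("fit_baselines needs the randomForest and e1071 packages")
  }
  x <- as.matrix(x)
  if (is.null(fold_assign)) {
    fold_assign <- make_cv_folds(nrow(x), folds, seed)
  }
  rf_grid <- expand.grid(trees = grids$rf_trees,
                         mtry = pmin(grids$rf_mtry, ncol(x)))
  rf_grid <- unique(rf_grid)
  rf_grid$spearman <- vapply(seq_len(nrow(rf_grid)), function(i) {
    set.seed(seed + i)   # deterministic forest per config
    cv_model_spearman(
      x, y, fold_assign,
      fit_fun = function(xt, yt) {
        randomForest::randomForest(xt, yt, ntree = rf_grid$trees[i],
                                   mtry = rf_grid$mtry[i])
      },
      predict_fun = function(fit, xt) {
        as.vector(stats::predict(fit, xt))
      })
  }, numeric(1))
  svm_grid <- expand.grid(cost = grids$svm_cost, gamma = grids$svm_gamma)
  svm_grid$spearman <- vapply(seq_len(nrow(svm_grid)), function(i) {
    cv_model_spearman(
      x, y, fold_assign,
      fit_fun = function(xt, yt) {
        e1071::svm(xt, yt, type = "eps-regression", kernel = "radial",
                   cost = svm_grid$cost[i], gamma = svm_grid$gamma[i])
      },
      predict_fun = function(fit, xt) {
        as.vector(stats::predict(fit, xt))
      })
  }, numeric(1))
  list(
    rfr = list(best = rf_grid[which.max(rf_grid$spearman), ],
               grid = rf_grid),
    svmr = list(best = svm_grid[which.max(svm_grid$spearman), ],
                grid = svm_grid),
    fold_assign = fold_assign)
}
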