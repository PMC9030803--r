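# k-fold cross-validation, the component sweep, ordered-subset curves and
# the per-family importance decomposition.

#' Build a k-fold assignment
#'
#' Seeded random permutation split into k near-equal folds; when n is not
#' divisible by k the remainder is distributed one-per-fold from the front
#' of the permutation.  With n = 85 and k = 5 every fold has exactly 17
#' samples.
#'
#' @param n Number of samples.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of length n with fold labels 1..k.
#' @export
make_cv_folds <- function(n, k, seed) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("more folds than samples")
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  if (min(sizes) < 3) stop("fold with fewer than 3 samples; reduce k")
  set.seed(seed)
  perm <- sample.int(n)
  assign <- integer(n)
  assign[perm] <- rep(seq_len(k), times = sizes)
  assign
}

cv_predictions <- function(x, y, n_components, fold_assign) {
  lapply(sort(unique(fold_assign)), function(f) {
    test <- fold_assign == f
    ncomp <- min(n_components, ncol(x), sum(!test) - 1)
    fit <- fit_plsr(x[!test, , drop = FALSE], y[!test], ncomp)
    list(obs = y[test], pred = predict(fit, x[test, , drop = FALSE]))
  })
}

# Mean held-out Spearman only; the hot path of the forward search.
cv_spearman <- function(x, y, n_components, fold_assign) {
  preds <- cv_predictions(x, y, n_components, fold_assign)
  mean(vapply(preds, function(p) spearman_gamma(p$obs, p$pred),
              numeric(1)))
}

#' Cross-validated evaluation of a PLSR model
#'
#' Fits the model on k-1 folds and evaluates the five metrics on each
#' held-out fold; per-fold metrics are averaged arithmetically.
#'
#' @param x Feature matrix (numeric matrix or `feature_matrix`).
#' @param y Response vector.
#' @param n_components PLSR components (clipped per fold to the training
#'   size and feature count).
#' @param folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @param fold_assign Optional precomputed assignment from
#'   [make_cv_folds()]; overrides `folds`/`seed`.
#' @param r2_form Passed to [regression_metrics()].
#' @return List with `per_fold` (data.frame of per-fold metrics) and
#'   `mean` (named vector of their averages).
#' @export
cross_validate <- function(x, y, n_components = 3, folds = 5, seed = 1,
                           fold_assign = NULL,
                           r2_form = "as_printed") {
  x <- as.matrix(x)
  if (is.null(fold_assign)) {
    fold_assign <- make_cv_folds(nrow(x), folds, seed)
  }
  preds <- cv_predictions(x, y, n_components, fold_assign)
  per_fold <- do.call(rbind, lapply(seq_along(preds), function(f) {
    m <- regression_metrics(preds[[f]]$obs, preds[[f]]$pred,
                            r2_form = r2_form)
    data.frame(fold = f, t(m))
  }))
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, setdiff(names(per_fold), "fold")]))
}

#' Sweep the number of PLSR components
#'
#' Cross-validates the model for each component count in `components`
#' on a shared fold assignment and reports the count maximizing the mean
#' held-out Spearman correlation.
#'
#' @inheritParams cross_validate
#' @param components Component counts to try, default 1:10.
#' @return List with `sweep` (data.frame: one row of mean metrics per
#'   component count) and `best_n_components`.
#' @export
sweep_components <- function(x, y, components = 1:10, folds = 5,
                             seed = 1, fold_assign = NULL) {
  x <- as.matrix(x)
  max_comp <- ncol(x)
  if (any(components > max_comp)) {
    warning("component range clipped to ", max_comp)
    components <- components[components <= max_comp]
  }
  if (is.null(fold_assign)) {
    fold_assign <- make_cv_folds(nrow(x), folds, seed)
  }
  rows <- lapply(components, function(a) {
    cv <- cross_validate(x, y, n_components = a,
                         fold_assign = fold_assign)
    data.frame(n_components = a, t(cv$mean))
  })
  sweep <- do.call(rbind, rows)
  list(sweep = sweep,
       best_n_components =
         sweep$n_components[which.max(sweep$spearman_gamma)])
}

#' Per-family importance of a selected feature subset
#'
#' Splits a feature subset into families (e.g. sequence composition /
#' physicochemical / structural), cross-validates a separate model per
#' family on shared folds, and reports each family's metrics.
#'
#' @inheritParams cross_validate
#' @param groups Named list mapping family name to feature names present
#'   in `colnames(x)`.
#' @return data.frame with one row of mean metrics per family (plus the
#'   family size).
#' @export
subset_importance <- function(x, y, groups, n_components = 3, folds = 5,
                              seed = 1, fold_assign = NULL) {
  x <- as.matrix(x)
  if (length(groups) == 0) stop("groups must be non-empty")
  if (is.null(fold_assign)) {
    fold_assign <- make_cv_folds(nrow(x), folds, seed)
  }
  rows <- lapply(names(groups), function(g) {
    feats <- groups[[g]]
    missing <- setdiff(feats, colnames(x))
    if (length(missing) > 0) {
      stop("family '", g, "': unknown feature(s) ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    cv <- cross_validate(x[, feats, drop = FALSE], y,
                         n_components = min(n_components, length(feats)),
                         fold_assign = fold_assign)
    data.frame(family = g, n_features = length(feats), t(cv$mean))
  })
  do.call(rbind, rows)
}

#' Score consecutive subsets of a feature ordering
#'
#' Partitions an ordered feature list into `n_subsets` consecutive blocks
#' of near-equal size and cross-validates a model on each block with
#' shared folds — a diagnostic of how information is distributed along a
#' ranking (front-loaded for a wrapper ordering, flat for a filter one).
#'
#' @inheritParams cross_validate
#' @param ordering Character vector of feature names in ranked order.
#' @param n_subsets Number of consecutive blocks, default 13.
#' @return data.frame with one row of mean metrics per block.
#' @export
ordered_subset_curve <- function(x, y, ordering, n_subsets = 13,
                                 n_components = 3, folds = 5, seed = 1,
                                 fold_assign = NULL) {
  x <- as.matrix(x)
  missing <- setdiff(ordering, colnames(x))
  if (length(missing) > 0) {
    stop("unknown feature(s) in ordering: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (is.null(fold_assign)) {
    fold_assign <- make_cv_folds(nrow(x), folds, seed)
  }
  p <- length(ordering)
  sizes <- rep(p %/% n_subsets, n_subsets)
  r <- p %% n_subsets
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  rows <- lapply(seq_len(n_subsets), function(b) {
    feats <- ordering[starts[b]:ends[b]]
    cv <- cross_validate(x[, feats, drop = FALSE], y,
                         n_components = min(n_components, length(feats)),
                         fold_assign = fold_assign)
    data.frame(subset = b, n_features = length(feats), t(cv$mean))
  })
  do.call(rbind, rows)
}
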