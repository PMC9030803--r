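# Model-wrapped greedy forward feature search.
#
# Starting from the first k_init features of the mRMR ordering, each step
# scores every remaining candidate by the cross-validated Spearman
# correlation of a PLSR model on the augmented subset and appends the
# argmax.  CV folds are frozen once per run so all candidates within (and
# across) steps are scored on identical partitions; ties break by
# ascending position in the candidate ordering.

#' Forward feature search wrapped around cross-validated PLSR
#'
#' @param x Normalized feature matrix (numeric matrix or
#'   `feature_matrix`).
#' @param y Response vector.
#' @param mrmr_order Character vector of feature names in mRMR order (from
#'   [rank_mrmr()]); supplies both the initial subset and the candidate
#'   ordering.
#' @param k_init Size of the initial subset taken from the head of
#'   `mrmr_order` (default 2: with 3 PLSR components the model needs at
#'   least 3 features, so scoring starts at the first addition).
#' @param n_components PLSR components for the evaluator (clipped to the
#'   current subset size).
#' @param max_features Stop once this many features are selected
#'   (clipped to the available pool with a warning).
#' @param folds,seed Cross-validation geometry; the fold assignment is
#'   drawn once and reused for every candidate evaluation.
#' @param pool_size Optional: restrict candidates to the first `pool_size`
#'   features of `mrmr_order` (the combined mRMR + forward protocol at
#'   reduced cost); default all.
#' @param evaluator Optional scoring function `function(feature_names) ->
#'   numeric` overriding the internal CV-Spearman evaluator (used for
#'   testing the search contract).
#' @return List of class `selection_state` with `selected` (ordered
#'   names), `initial` (the k_init seed features), `trace` (data.frame:
#'   step, feature, score) and `fold_assign`.
#' @export
forward_search <- function(x, y, mrmr_order, k_init = 2,
                           n_components = 3, max_features = 30,
                           folds = 5, seed = 1, pool_size = NULL,
                           evaluator = NULL) {
  x <- as.matrix(x)
  if (k_init < 1) stop("k_init must be >= 1")
  missing <- setdiff(mrmr_order, colnames(x))
  if (length(missing) > 0) {
    stop("mrmr_order names absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  pool <- if (is.null(pool_size)) {
    mrmr_order
  } else {
    utils::head(mrmr_order, pool_size)
  }
  if (k_init > length(pool)) stop("k_init exceeds the candidate pool")
  if (max_features > length(pool)) {
    warning("max_features clipped to pool size ", length(pool))
    max_features <- length(pool)
  }
  fold_assign <- make_cv_folds(nrow(x), folds, seed)
  if (is.null(evaluator)) {
    evaluator <- function(feats) {
      cv_spearman(x[, feats, drop = FALSE], y,
                  min(n_components, length(feats)), fold_assign)
    }
  }
  selected <- pool[seq_len(k_init)]
  remaining <- pool[-seq_len(k_init)]
  trace <- data.frame(step = integer(0), feature = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  while (length(selected) < max_features && length(remaining) > 0) {
    step <- step + 1L
    scores <- vapply(remaining, function(f) evaluator(c(selected, f)),
                     numeric(1))
    best <- which.max(scores)   # first max: stable tie-break
    trace <- rbind(trace, data.frame(
      step = step, feature = remaining[best], score = scores[best],
      stringsAsFactors = FALSE))
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  rownames(trace) <- NULL
  structure(list(selected = selected,
                 initial = pool[seq_len(k_init)],
                 trace = trace, remaining = remaining,
                 fold_assign = fold_assign,
                 n_components = n_components),
            class = "selection_state")
}

#' @export
print.selection_state <- function(x, ...) {
  cat("<selection_state> ", length(x$selected), " features selected (",
      length(x$initial), " seeded); best step score ",
      if (nrow(x$trace) > 0) format(max(x$trace$score), digits = 3)
      else "NA", "\n", sep = "")
  invisible(x)
}
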