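# Partial least squares regression (PLS1) via NIPALS.
#
# For a single response the NIPALS inner loop converges immediately, but
# the generic iteration (tolerance 1e-10, max 500 iterations) is kept so
# the extraction is the documented algorithm.  X and y are centered but
# not rescaled here; feed z-scored matrices for the full protocol.

#' Fit a partial least squares regression model
#'
#' Extracts `n_components` latent components by NIPALS: at each step the
#' X-weight vector is the (normalized) covariance direction between the
#' deflated X and y, scores are projections on it, and X is deflated by
#' the rank-one score/loading outer product.  Prediction is linear in X.
#'
#' @param x Numeric matrix, samples x features.
#' @param y Numeric response vector.
#' @param n_components Number of latent components, at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @param tol Inner-loop convergence tolerance on the score vector.
#' @param max_iter Maximum inner iterations per component.
#' @return An object of class `plsr_model`.
#' @export
fit_plsr <- function(x, y, n_components, tol = 1e-10, max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components > p) {
    stop("n_components (", n_components, ") exceeds number of features (",
         p, ")")
  }
  if (n_components > n - 1) {
    stop("n_components must be <= n_samples - 1")
  }
  x_means <- colMeans(x)
  y_mean <- mean(y)
  E <- sweep(x, 2, x_means)
  f <- y - y_mean
  if (all(abs(E) < 1e-300)) stop("X is constant after centering")
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  actual <- 0L
  for (a in seq_len(n_components)) {
    u <- f
    t_old <- rep(Inf, n)
    for (iter in seq_len(max_iter)) {
      w <- crossprod(E, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) break
      w <- w / wn
      t_vec <- E %*% w
      if (sqrt(sum((t_vec - t_old)^2)) < tol) break
      t_old <- t_vec
      qq <- sum(f * t_vec) / sum(t_vec^2)
      u <- f * qq
    }
    if (wn < 1e-14 || sum(t_vec^2) < 1e-14) {
      warning("component extraction stopped early at ", a - 1L,
              " components (X residual exhausted)")
      break
    }
    tt <- sum(t_vec^2)
    p_vec <- crossprod(E, t_vec) / tt
    q[a] <- sum(f * t_vec) / tt
    E <- E - t_vec %*% t(p_vec)
    f <- f - as.vector(t_vec) * q[a]
    W[, a] <- w
    P[, a] <- p_vec
    actual <- a
  }
  if (actual == 0L) stop("no component could be extracted")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  q <- q[seq_len(actual)]
  # regression coefficients in original (centered) X space
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(n_components = actual, x_weights = W, x_loadings = P,
                 y_loadings = q, coefficients = as.vector(beta),
                 x_means = x_means, y_mean = y_mean,
                 feature_names = colnames(x)),
            class = "plsr_model")
}

#' Predict from a fitted PLSR model
#'
#' @param object A `plsr_model`.
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Ignored.
#' @return Numeric vector of predictions, one per row.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_means)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$x_means))
  }
  xc <- sweep(newdata, 2, object$x_means)
  as.vector(xc %*% object$coefficients) + object$y_mean
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("<plsr_model> ", x$n_components, " components, ",
      length(x$x_means), " features\n", sep = "")
  invisible(x)
}
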