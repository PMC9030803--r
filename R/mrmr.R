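# Minimum-redundancy-maximum-relevance feature ranking.
#
# Features and target are discretized into three states (below / within /
# above a mean +- sigma_mult * sd band) and scored by plug-in mutual
# information in nats.  The maxRel list sorts by relevance alone; the mRMR
# list is built greedily, at each step maximizing relevance minus (or
# divided by) the mean redundancy with already-selected features.

#' Discretize a continuous vector into three states
#'
#' State 0 below `mean - sigma_mult * sd`, state 2 above
#' `mean + sigma_mult * sd`, state 1 inside the band.  On z-scored input
#' with `sigma_mult = 0.5` the thresholds sit at -0.5 and +0.5 exactly.
#'
#' @param values Numeric vector with positive variance.
#' @param sigma_mult Half-width of the central band in sd units.
#' @return Integer vector over {0, 1, 2}.
#' @export
discretize3 <- function(values, sigma_mult = 0.5) {
  s <- stats::sd(values)
  if (s == 0) stop("cannot discretize a zero-variance vector")
  m <- mean(values)
  out <- integer(length(values))
  out[values < m - sigma_mult * s] <- 0L
  out[values >= m - sigma_mult * s & values <= m + sigma_mult * s] <- 1L
  out[values > m + sigma_mult * s] <- 2L
  out
}

# fast plug-in MI for two vectors over {0,1,2}
mi3 <- function(a, b) {
  counts <- tabulate(a * 3L + b + 1L, nbins = 9L)
  n <- length(a)
  pj <- counts / n
  pA <- c(sum(pj[1:3]), sum(pj[4:6]), sum(pj[7:9]))
  pB <- c(sum(pj[c(1, 4, 7)]), sum(pj[c(2, 5, 8)]), sum(pj[c(3, 6, 9)]))
  mi <- 0
  for (i in 0:2) {
    for (j in 0:2) {
      p <- pj[i * 3 + j + 1]
      if (p > 0) mi <- mi + p * log(p / (pA[i + 1] * pB[j + 1]))
    }
  }
  mi
}

#' Plug-in mutual information of two discrete vectors
#'
#' Empirical mutual information (in nats) from the joint distribution of
#' two equal-length discrete vectors; nonnegative and symmetric.
#'
#' @param a,b Vectors coercible to factors, equal length >= 2.
#' @return Mutual information in nats.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2) stop("need at least 2 observations")
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      p <- tab[i, j]
      if (p > 0) mi <- mi + p * log(p / (pa[i] * pb[j]))
    }
  }
  as.numeric(mi)
}

#' mRMR feature ranking
#'
#' Computes the relevance (mutual information with the discretized target)
#' of every feature and produces two orderings: the maxRel list (relevance
#' descending) and the mRMR list (greedy; first feature maximizes
#' relevance, each further step maximizes relevance minus mean redundancy
#' under the `difference` scheme, or relevance over mean redundancy under
#' `quotient`, where redundancy is the mean MI with already-selected
#' features).  Ties break by ascending column position.
#'
#' @param x Normalized feature matrix (numeric matrix or
#'   `feature_matrix`).
#' @param y Response vector.
#' @param scheme `"difference"` (MID, default) or `"quotient"` (MIQ).
#' @param sigma_mult Discretization band half-width, default 0.5.
#' @param n_select Stop the greedy mRMR ordering after this many features
#'   (default: rank all).
#' @return List with `maxrel_order`, `mrmr_order` (character vectors of
#'   feature names), `relevance` (named numeric) and `scheme`.
#' @export
rank_mrmr <- function(x, y, scheme = c("difference", "quotient"),
                      sigma_mult = 0.5, n_select = NULL) {
  scheme <- match.arg(scheme)
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("mRMR requires at least 2 features")
  if (is.null(n_select)) n_select <- p
  n_select <- min(n_select, p)
  D <- apply(x, 2, discretize3, sigma_mult = sigma_mult)
  dy <- discretize3(y, sigma_mult = sigma_mult)
  rel <- vapply(seq_len(p), function(j) mi3(D[, j], dy), numeric(1))
  names(rel) <- colnames(x)
  maxrel_order <- colnames(x)[order(-rel)]   # stable: ties by position
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)
  first <- remaining[which.max(rel[remaining])]
  selected <- first
  remaining <- setdiff(remaining, first)
  while (length(selected) < n_select && length(remaining) > 0) {
    last <- selected[length(selected)]
    red_sum[remaining] <- red_sum[remaining] +
      vapply(remaining, function(j) mi3(D[, j], D[, last]), numeric(1))
    red <- red_sum[remaining] / length(selected)
    score <- if (scheme == "difference") {
      rel[remaining] - red
    } else {
      rel[remaining] / pmax(red, .Machine$double.eps)
    }
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  list(maxrel_order = maxrel_order,
       mrmr_order = colnames(x)[selected],
       relevance = rel, scheme = scheme, sigma_mult = sigma_mult)
}
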