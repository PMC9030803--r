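# Discretization, mutual information and mRMR ranking.

test_that("three-state discretization thresholds sit at mean +- k sd", {
  z <- c(-2, -0.6, -0.5, 0, 0.5, 0.6, 2)
  z <- z - mean(z)            # mean 0
  z <- z / sd(z)              # sd 1 -> thresholds exactly -+0.5
  d <- discretize3(z, sigma_mult = 0.5)
  expected <- ifelse(z < -0.5, 0L, ifelse(z <= 0.5, 1L, 2L))
  expect_equal(d, expected)

  # everything inside the band is state 1
  expect_true(all(discretize3(c(0.1, 0.11, 0.12, 0.1), 5) == 1L))
  expect_error(discretize3(rep(1, 5)), "zero-variance")
})

test_that("symmetric data puts states 0 and 2 at equal frequency", {
  set.seed(1)
  x <- rnorm(1e5)
  d <- discretize3(x, 0.5)
  f0 <- mean(d == 0)
  f2 <- mean(d == 2)
  expect_equal(f0, f2, tolerance = 0.02)
  expect_equal(f0, pnorm(-0.5), tolerance = 0.02)
})

test_that("mutual information has the right identities", {
  a <- rep(0:2, each = 30)
  expect_equal(mutual_information(a, a), log(3), tolerance = 1e-12)

  set.seed(2)
  u <- sample(0:2, 1e5, replace = TRUE)
  v <- sample(0:2, 1e5, replace = TRUE)
  expect_lt(mutual_information(u, v), 0.01)
  expect_equal(mutual_information(u, v), mutual_information(v, u))
  expect_gte(mutual_information(u, v), 0)
  expect_error(mutual_information(1:3, 1:4), "length")

  # the fast 3-state path agrees with the generic implementation
  for (s in 1:20) {
    set.seed(s)
    a <- sample(0:2, 200, replace = TRUE)
    b <- (a + sample(0:1, 200, replace = TRUE, prob = c(0.7, 0.3))) %% 3L
    expect_equal(splicefactoR:::mi3(a, b), mutual_information(a, b),
                 tolerance = 1e-12)
  }
})

test_that("mRMR demotes an exact copy below an independent feature", {
  set.seed(3)
  n <- 500
  x1 <- rnorm(n)
  x <- cbind(X1 = x1, X2 = x1, X3 = rnorm(n))
  rownames(x) <- seq_len(n)
  y <- x1 + rnorm(n, 0, 0.3)
  res <- rank_mrmr(x, y, scheme = "difference")
  expect_equal(res$maxrel_order[1:2], c("X1", "X2"))
  # redundancy MI(X2, X1) = H(X1) dominates, so X3 is picked before X2
  expect_equal(res$mrmr_order, c("X1", "X3", "X2"))
})

test_that("a single informative feature ranks first in both lists", {
  for (s in 1:10) {
    set.seed(s)
    n <- 300
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("F", 1:10)))
    y <- x[, "F7"] + rnorm(n, 0, 0.2)
    rownames(x) <- seq_len(n)
    res <- rank_mrmr(x, y)
    expect_equal(res$maxrel_order[1], "F7")
    expect_equal(res$mrmr_order[1], "F7")
  }
})

test_that("independent features keep the maxRel order under mRMR", {
  set.seed(4)
  n <- 2000
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(seq_len(n), paste0("F", 1:6)))
  y <- rowSums(x %*% diag(c(3, 2.5, 2, 1.5, 1, 0.5))) + rnorm(n, 0, 0.1)
  res <- rank_mrmr(x, y)
  # with near-zero pairwise redundancy the greedy order tracks relevance
  expect_equal(res$mrmr_order, res$maxrel_order)
})

test_that("greedy mRMR equals exhaustive per-step argmax (oracle)", {
  set.seed(5)
  n <- 200
  p <- 12
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(seq_len(n), paste0("F", 1:p)))
  x[, 2] <- x[, 1] + rnorm(n, 0, 0.4)     # induce redundancy structure
  x[, 5] <- -x[, 3] + rnorm(n, 0, 0.4)
  y <- x[, 1] + x[, 3] + rnorm(n, 0, 0.5)
  res <- rank_mrmr(x, y, scheme = "difference")

  # oracle: entropy-based MI, explicit per-step exhaustive argmax
  ent <- function(v) {
    pr <- table(v) / length(v)
    -sum(pr * log(pr))
  }
  mi_oracle <- function(a, b) ent(a) + ent(b) - ent(paste(a, b))
  D <- apply(x, 2, discretize3, sigma_mult = 0.5)
  dy <- discretize3(y, 0.5)
  rel <- vapply(seq_len(p), function(j) mi_oracle(D[, j], dy),
                numeric(1))
  sel <- which.max(rel)
  while (length(sel) < p) {
    rest <- setdiff(seq_len(p), sel)
    score <- vapply(rest, function(j) {
      red <- mean(vapply(sel, function(s) mi_oracle(D[, j], D[, s]),
                         numeric(1)))
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, rest[which.max(score)])
  }
  expect_equal(res$mrmr_order, colnames(x)[sel])
})
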