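# Fold geometry, cross-validation, the component sweep, ordered-subset
# curves and per-family importance.

test_that("fold assignment partitions the cohort near-equally", {
  f <- make_cv_folds(85, 5, seed = 1)
  expect_equal(as.vector(table(f)), rep(17L, 5))

  f2 <- make_cv_folds(23, 4, seed = 2)
  expect_equal(sort(as.vector(table(f2))), c(5L, 6L, 6L, 6L))
  expect_equal(sort(unique(f2)), 1:4)

  expect_identical(make_cv_folds(40, 5, 7), make_cv_folds(40, 5, 7))
  expect_false(identical(make_cv_folds(40, 5, 7),
                         make_cv_folds(40, 5, 8)))
  expect_error(make_cv_folds(10, 1, 1), ">= 2")
  expect_error(make_cv_folds(11, 5, 1), "fewer than 3")
})

test_that("cross-validation averages per-fold metrics and is seeded", {
  set.seed(1)
  x <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("p%02d", 1:50), paste0("F", 1:8)))
  y <- x[, 1] - x[, 2] + rnorm(50, 0, 0.3)
  cv1 <- cross_validate(x, y, n_components = 3, folds = 5, seed = 9)
  cv2 <- cross_validate(x, y, n_components = 3, folds = 5, seed = 9)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$per_fold), 5)
  expect_equal(unname(cv1$mean["spearman_gamma"]),
               mean(cv1$per_fold$spearman_gamma))
})

test_that("the component sweep peaks near the latent dimension", {
  d <- simulate_latent_design(n = 100, p = 40, n_factors = 3, seed = 5)
  sw <- sweep_components(d$x, d$y, components = 1:10, folds = 5,
                         seed = 1)
  expect_equal(nrow(sw$sweep), 10)
  expect_lte(abs(sw$best_n_components - 3), 1)
  # requesting more components than features is clipped with a warning
  expect_warning(
    sweep_components(d$x[, 1:4], d$y, components = 1:10, seed = 1),
    "clipped")
})

test_that("a pure-noise response stays inside the null envelope", {
  set.seed(6)
  x <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, paste0("F", 1:10)))
  rownames(x) <- seq_len(60)
  y <- rnorm(60)
  sw <- sweep_components(x, y, components = 1:6, folds = 5, seed = 1)
  null_best <- vapply(1:9, function(i) {
    set.seed(200 + i)
    max(sweep_components(x, sample(y), components = 1:6, folds = 5,
                         seed = 1)$sweep$spearman_gamma)
  }, numeric(1))
  expect_lte(max(sw$sweep$spearman_gamma), max(null_best) + 0.05)
})

test_that("ordered-subset curves split a ranking into 13 blocks", {
  set.seed(7)
  x <- matrix(rnorm(60 * 40), 60, 40,
              dimnames = list(seq_len(60), sprintf("F%02d", 1:40)))
  y <- x[, 1] + rnorm(60)
  curve <- ordered_subset_curve(x, y, colnames(x), n_subsets = 13,
                                folds = 5, seed = 1)
  expect_equal(nrow(curve), 13)
  expect_equal(sum(curve$n_features), 40)
  expect_true(all(abs(curve$n_features - 40 / 13) < 1.5))
  expect_error(ordered_subset_curve(x, y, c("F01", "nope")), "unknown")
})

test_that("the family holding the planted features scores highest", {
  d <- small_cohort(n = 60, seed = 8, noise_sd = 0.1,
                    planted = c("Dual-AAC_GT", "AAC_K"),
                    weights = c(1, 0.8))
  fm <- zscore_features(drop_near_zero(
    assemble_features(d$proteins, d$profiles)))
  groups <- list(
    sequence = intersect(c("Dual-AAC_GT", "AAC_K", "AAC_A", "Dual-AAC_LL"),
                         colnames(fm$x)),
    structural = intersect(c("SS3_composition_H", "SS8_Dual_GG",
                             "ASA-1th", "CN-2th"), colnames(fm$x)))
  imp <- subset_importance(fm, d$proteins$activity, groups,
                           n_components = 2, folds = 5, seed = 1)
  expect_equal(nrow(imp), 2)
  expect_gt(imp$spearman_gamma[imp$family == "sequence"],
            imp$spearman_gamma[imp$family == "structural"])
  expect_error(subset_importance(fm, d$proteins$activity,
                                 list(bad = "NotThere")), "unknown")
})
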