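# Feature-matrix assembly, near-zero filtering and z-scoring.

test_that("assembly produces the 700-column schema in order", {
  d <- small_cohort(n = 3, seed = 2)
  fm <- assemble_features(d$proteins, d$profiles)
  expect_equal(ncol(fm$x), 700)
  expect_equal(colnames(fm$x), feature_schema())
  expect_equal(rownames(fm$x), d$proteins$id)
  expect_false(anyNA(fm$x))

  # cohort of one still works
  fm1 <- assemble_features(d$proteins[1, ], d$profiles[1])
  expect_equal(dim(fm1$x), c(1L, 700L))

  # a protein without a profile is an error naming it
  expect_error(assemble_features(d$proteins, d$profiles[-2]),
               d$proteins$id[2])
})

test_that("profile/sequence length mismatches are detected", {
  d <- small_cohort(n = 2, seed = 4)
  short <- d$proteins
  short$sequence[1] <- substr(short$sequence[1], 1, 10)
  expect_error(assemble_features(short, d$profiles), "10 residues")
})

test_that("near-zero filtering removes exactly the sub-epsilon columns", {
  x <- matrix(runif(10 * 700, min = 0.1, max = 1), 10, 700,
              dimnames = list(sprintf("p%02d", 1:10), feature_schema()))
  zero_cols <- sample(700, 53)
  x[, zero_cols] <- 0
  fm <- splicefactoR:::new_feature_matrix(x)
  filt <- drop_near_zero(fm, epsilon = 1e-8)
  expect_equal(ncol(filt$x), 647)   # mirrors a 700 -> 647 reduction
  expect_setequal(filt$dropped, feature_schema()[zero_cols])
  # surviving order preserved
  expect_equal(colnames(filt$x),
               setdiff(feature_schema(), feature_schema()[zero_cols]))

  # epsilon = 0 removes nothing (strict inequality), even exact zeros
  none <- drop_near_zero(fm, epsilon = 0, drop_constant = FALSE)
  expect_equal(ncol(none$x), 700)
})

test_that("z-scoring matches the closed form and inverts exactly", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 4, 8))
  rownames(x) <- c("p1", "p2", "p3")
  fm <- splicefactoR:::new_feature_matrix(x)
  z <- zscore_features(fm)
  expect_equal(unname(z$x[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z$x)), c(0, 0))
  expect_equal(unname(apply(z$x, 2, sd)), c(1, 1))

  # idempotence on the stats: re-scoring an already-normalized column
  z2 <- zscore_features(splicefactoR:::new_feature_matrix(z$x))
  expect_equal(z2$x, z$x, tolerance = 1e-12)

  # exact inverse transform
  back <- inverse_zscore(z)
  expect_equal(back$x, x, tolerance = 1e-10)

  # constant columns are an error naming the column
  bad_x <- cbind(a = c(1, 2, 3), flat = c(7, 7, 7))
  rownames(bad_x) <- paste0("p", 1:3)
  bad <- splicefactoR:::new_feature_matrix(bad_x)
  expect_error(zscore_features(bad), "flat")
})

test_that("feature matrix TSV round-trips", {
  d <- small_cohort(n = 4, seed = 6)
  fm <- assemble_features(d$proteins, d$profiles)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
})
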