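# The synthetic-cohort generator.

test_that("sequence simulation is deterministic and honors the spec", {
  spec <- simulation_spec(n_proteins = 10, length_range = c(20, 60),
                         rng_seed = 1)
  p1 <- simulate_proteins(spec)
  p2 <- simulate_proteins(spec)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10)
  lens <- nchar(p1$sequence)
  expect_true(all(lens >= 20 & lens <= 60))

  # degenerate composition bias
  spec_a <- simulation_spec(n_proteins = 3, length_range = c(5, 10),
                            composition_bias = c(A = 1), rng_seed = 2)
  pa <- simulate_proteins(spec_a)
  expect_true(all(grepl("^A+$", pa$sequence)))

  # empty cohort
  spec0 <- simulation_spec(n_proteins = 0)
  expect_equal(nrow(simulate_proteins(spec0)), 0)
})

test_that("simulated profiles satisfy the structural invariants", {
  spec <- simulation_spec(n_proteins = 6, length_range = c(30, 80),
                          rng_seed = 3)
  prot <- simulate_proteins(spec)
  prof <- simulate_profiles(prot, spec)
  prof2 <- simulate_profiles(prot, spec)
  expect_identical(prof, prof2)

  argmax_hits <- 0
  n_rows <- 0
  for (i in seq_len(nrow(prot))) {
    p <- prof[[prot$id[i]]]
    expect_equal(length(p$aa), nchar(prot$sequence[i]))
    expect_equal(p$ss3, condense_ss8(p$ss8))
    expect_true(all(abs(rowSums(p$ss3_probs) - 1) < 1e-3))
    expect_true(all(abs(rowSums(p$ss8_probs) - 1) < 1e-3))
    expect_true(all(p$asa >= 0 & p$asa <= 250))
    expect_true(all(p$hse_up >= 0 & p$hse_down >= 0 & p$cn >= 0))
    for (tr in c("theta", "tau", "phi", "psi")) {
      expect_true(all(p[[tr]] > -180 & p[[tr]] <= 180))
    }
    hits <- colnames(p$ss8_probs)[max.col(p$ss8_probs)] == p$ss8
    argmax_hits <- argmax_hits + sum(hits)
    n_rows <- n_rows + length(hits)
  }
  # probability tracks are concentrated on the drawn label
  expect_gt(argmax_hits / n_rows, 0.95)
})

test_that("planted activities reproduce the linear construction", {
  # noise 0, one planted feature: correlation with the feature is 1
  spec <- simulation_spec(n_proteins = 15, length_range = c(30, 80),
                          planted_features = "AAC_A",
                          planted_weights = 2, noise_sd = 0,
                          rng_seed = 4)
  d <- simulate_dataset(spec)
  fm <- assemble_features(d$proteins, d$profiles)
  expect_equal(cor(d$proteins$activity, fm$x[, "AAC_A"]), 1,
               tolerance = 1e-12)

  # unknown planted feature names are rejected with guidance
  expect_error(simulation_spec(planted_features = "NotAFeature",
                               planted_weights = 1),
               "feature_schema")
})

test_that("a zero-weight cohort carries no recoverable signal", {
  spec <- simulation_spec(n_proteins = 100, length_range = c(40, 100),
                          planted_features = "AAC_A",
                          planted_weights = 0, noise_sd = 1,
                          rng_seed = 5)
  d <- simulate_dataset(spec)
  y <- d$proteins$activity
  expect_gt(sd(y), 0)
  fm <- zscore_features(drop_near_zero(
    assemble_features(d$proteins, d$profiles)))

  # forward search on the true y gains nothing significant over the same
  # search on permuted y (null envelope from 9 permutations)
  run_best <- function(target, seed) {
    mr <- rank_mrmr(fm, target, n_select = 12)
    fw <- forward_search(fm, target, mr$mrmr_order, max_features = 4,
                         pool_size = 12, seed = seed)
    max(fw$trace$score)
  }
  obs <- run_best(y, seed = 1)
  null_scores <- vapply(1:9, function(i) {
    set.seed(100 + i)
    run_best(sample(y), seed = 1)
  }, numeric(1))
  expect_lte(obs, max(null_scores) + 0.05)
})
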