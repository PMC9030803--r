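# Structure-derived descriptors.

test_that("pseudosequence feature counts are 27 (SS3) and 112 (SS8)", {
  ss3 <- sample(c("H", "E", "C"), 30, replace = TRUE)
  ss8 <- sample(c("G", "H", "I", "B", "E", "S", "T", "C"), 30,
                replace = TRUE)
  expect_equal(length(pseudoseq_features(ss3, c("H", "E", "C"), "SS3")),
               27)
  expect_equal(length(pseudoseq_features(
    ss8, c("G", "H", "I", "B", "E", "S", "T", "C"), "SS8")), 112)
  expect_error(pseudoseq_features(c("H", "X"), c("H", "E", "C"), "SS3"),
               "outside")
})

test_that("single-state pseudosequence gives one-hot composition and dual", {
  v <- pseudoseq_features(rep("C", 4), c("H", "E", "C"), "SS3")
  expect_equal(unname(v["SS3_composition_C"]), 1)
  expect_equal(unname(v["SS3_Dual_CC"]), 1)
  expect_equal(unname(v[paste0("SS3_distribution_C-",
                               c("0.0", "0.25", "0.5", "0.75", "1.0"))]),
               c(0.25, 0.25, 0.5, 0.75, 1.0))
  expect_equal(sum(v[startsWith(names(v), "SS3_composition")]), 1)
})

test_that("three-part means follow the floor boundary rule", {
  expect_equal(three_part_means(c(0, 0, 1, 1, 0, 0)), c(0, 1, 0))
  expect_equal(three_part_means(rep(5, 11)), c(5, 5, 5))
  # L = 7: parts {1,2}, {3,4}, {5,6,7}
  expect_equal(three_part_means(1:7), c(1.5, 3.5, 6.0))
  expect_error(three_part_means(1:2), ">= 3")
})

test_that("the structural encoding has 196 features with a 172 SS block", {
  prof <- make_profile(strsplit(random_sequence(25, 3), "")[[1]])
  v <- encode_structure(prof)
  expect_equal(length(v), 196)
  ss_block <- grepl("^SS[38]_", names(v))
  expect_equal(sum(ss_block), 172)
  expect_equal(sum(startsWith(names(v), "SS3_")), 36)
  expect_equal(sum(startsWith(names(v), "SS8_")), 136)
  expect_equal(sum(!ss_block), 24)
  # composition blocks sum to 1; probability part-means lie in [0,1]
  expect_equal(sum(v[startsWith(names(v), "SS3_composition")]), 1)
  expect_equal(sum(v[startsWith(names(v), "SS8_composition")]), 1)
  probs <- v[grepl("^SS[38]_prob_", names(v))]
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("all-coil profile with p_C = 1 yields unit coil features", {
  aa <- strsplit(random_sequence(12, 5), "")[[1]]
  prof <- make_profile(aa, ss8 = rep("C", 12))
  v <- encode_structure(prof)
  expect_equal(unname(v["SS3_composition_C"]), 1)
  expect_equal(unname(v[paste0("SS3_prob_C-", 1:3, "th")]), rep(1, 3))
})

test_that("reversal preserves SS composition features", {
  aa <- strsplit(random_sequence(20, 7), "")[[1]]
  ss8 <- sample(c("G", "H", "E", "C", "T"), 20, replace = TRUE)
  p1 <- make_profile(aa, ss8 = ss8)
  p2 <- make_profile(rev(aa), ss8 = rev(ss8))
  v1 <- encode_structure(p1)
  v2 <- encode_structure(p2)
  keep <- grepl("^SS[38]_composition_", names(v1))
  expect_equal(v1[keep], v2[keep])
})

test_that("profiles shorter than 3 residues are rejected", {
  prof <- make_profile(c("M", "K"))
  expect_error(encode_structure(prof), ">= 3")
})
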