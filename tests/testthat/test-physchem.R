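# CTD physicochemical descriptors.

test_that("pseudosequence recoding follows the hydrophobicity grouping", {
  g <- ctd_groupings()$Hydrophobicity
  expect_equal(to_pseudosequence("RKED", g), "PPPP")
  expect_equal(to_pseudosequence("CLVI", g), "HHHH")
  expect_equal(to_pseudosequence("GASTP", g), "NNNNN")
})

test_that("every grouping partitions the 20-letter alphabet", {
  for (g in ctd_groupings()) {
    letters_all <- sort(unname(unlist(g$groups)))
    expect_equal(letters_all, sort(aa_letters()))
  }
  # an overlapping/incomplete grouping is rejected at construction
  expect_error(
    splicefactoR:::validate_grouping("bad",
                                     list(P = c("A"), N = c("A"),
                                          H = aa_letters())),
    "partition")
})

test_that("CTD composition and transition match hand counts", {
  expect_equal(unname(ctd_composition("PPNH")), c(0.5, 0.25, 0.25))
  expect_equal(unname(ctd_composition("PPPP")), c(1, 0, 0))
  expect_equal(unname(ctd_composition("PNH")), rep(1 / 3, 3))

  expect_equal(unname(ctd_transition("PHPH")), c(0, 1, 0))
  expect_equal(unname(ctd_transition("PPPP")), c(0, 0, 0))
  expect_equal(unname(ctd_transition("PNH")), c(0.5, 0, 0.5))
})

test_that("CTD distribution uses the five-anchor occurrence quantiles", {
  v <- ctd_distribution("PPPP")
  expect_equal(unname(v[1:5]), c(0.25, 0.25, 0.5, 0.75, 1.0))
  expect_true(all(v[6:15] == 0))

  # P occurs at positions 2,3 of length 4: anchors at occurrences
  # (1,1,1,2,2) -> positions (2,2,2,3,3)/4
  v <- ctd_distribution("NPPN")
  expect_equal(unname(v[1:5]), c(0.5, 0.5, 0.5, 0.75, 0.75))
})

test_that("distribution values are in [0,1] and non-decreasing per symbol", {
  for (s in 1:40) {
    set.seed(s)
    pseudo <- paste(sample(c("P", "N", "H"), sample(3:50, 1),
                           replace = TRUE), collapse = "")
    v <- ctd_distribution(pseudo)
    expect_true(all(v >= 0 & v <= 1))
    for (k in 0:2) {
      expect_true(all(diff(v[k * 5 + 1:5]) >= 0))
    }
  }
})

test_that("the full physicochemical encoding has 84 features, 21 per property", {
  v <- encode_physchem(random_sequence(40, seed = 9))
  expect_equal(length(v), 84)
  expect_false(anyDuplicated(names(v)) > 0)
  for (prop in names(ctd_groupings())) {
    expect_equal(sum(startsWith(names(v), paste0(prop, "_"))), 21)
    comp <- v[paste0(prop, "_composition_", c("P", "N", "H"))]
    expect_equal(sum(comp), 1)
    trans <- v[paste0(prop, "_transition_", c("PN", "PH", "NH"))]
    expect_true(sum(trans) <= 1 + 1e-12)
  }
})

test_that("reversal preserves composition and transition features", {
  seq <- random_sequence(60, seed = 17)
  rev_seq <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
  v1 <- encode_physchem(seq)
  v2 <- encode_physchem(rev_seq)
  keep <- grepl("_(composition|transition)_", names(v1))
  expect_equal(v1[keep], v2[keep])
})

test_that("CTD encoder agrees with a naive position-scanning oracle", {
  naive_ctd <- function(seq, grouping) {
    chars <- strsplit(seq, "")[[1]]
    sym <- vapply(chars, function(ch) {
      for (s in names(grouping$groups)) {
        if (ch %in% grouping$groups[[s]]) return(s)
      }
      stop("unmapped")
    }, character(1))
    L <- length(sym)
    comp <- vapply(c("P", "N", "H"), function(s) mean(sym == s),
                   numeric(1))
    pairs <- list(c("P", "N"), c("P", "H"), c("N", "H"))
    trans <- vapply(pairs, function(pr) {
      cnt <- 0
      for (k in seq_len(L - 1)) {
        if ((sym[k] == pr[1] && sym[k + 1] == pr[2]) ||
            (sym[k] == pr[2] && sym[k + 1] == pr[1])) cnt <- cnt + 1
      }
      cnt / (L - 1)
    }, numeric(1))
    dist <- numeric(0)
    for (s in c("P", "N", "H")) {
      pos <- which(sym == s)
      if (length(pos) == 0) {
        dist <- c(dist, rep(0, 5))
      } else {
        for (q in c(0, 0.25, 0.5, 0.75, 1)) {
          idx <- max(1, ceiling(q * length(pos)))
          dist <- c(dist, pos[idx] / L)
        }
      }
    }
    c(comp, trans, dist)
  }
  groupings <- ctd_groupings()
  for (s in 1:100) {
    seq <- random_sequence(sample(2:50, 1), seed = 1000 + s)
    g <- groupings[[sample(4, 1)]]
    pseudo <- to_pseudosequence(seq, g)
    got <- unname(c(ctd_composition(pseudo), ctd_transition(pseudo),
                    ctd_distribution(pseudo)))
    expect_equal(got, unname(naive_ctd(seq, g)))
  }
})
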