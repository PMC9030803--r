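# Shared fixtures: tiny deterministic profiles and random sequences.

aa_letters <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

random_sequence <- function(len, seed) {
  set.seed(seed)
  paste(sample(aa_letters(), len, replace = TRUE), collapse = "")
}

# A fully deterministic profile with one-hot probability tracks and simple
# continuous tracks; ss8 defaults to a mix covering several states.
make_profile <- function(aa, ss8 = NULL, id = "p1") {
  L <- length(aa)
  if (is.null(ss8)) {
    ss8 <- rep(c("H", "E", "C", "G", "T"), length.out = L)
  }
  ss3 <- condense_ss8(ss8)
  ss3_states <- c("C", "E", "H")
  ss8_states <- c("G", "H", "I", "B", "E", "S", "T", "C")
  ss3_probs <- t(vapply(ss3, function(s) {
    as.numeric(ss3_states == s)
  }, numeric(3)))
  ss8_probs <- t(vapply(ss8, function(s) {
    as.numeric(ss8_states == s)
  }, numeric(8)))
  structural_profile(
    protein_id = id, aa = aa, ss8 = ss8,
    ss3_probs = ss3_probs, ss8_probs = ss8_probs,
    asa = seq(10, 200, length.out = L),
    hse_up = rep(10, L), hse_down = rep(12, L), cn = rep(25, L),
    theta = rep(100, L), tau = rep(-50, L), phi = rep(-70, L),
    psi = rep(120, L))
}

# Small labelled cohort for pipeline-level tests.
small_cohort <- function(n = 20, seed = 11, noise_sd = 0,
                         planted = c("AAC_A",
                                     "Hydrophobicity_distribution_H-0.0"),
                         weights = c(1, 0.6),
                         len_range = c(40, 120)) {
  spec <- simulation_spec(
    n_proteins = n, length_range = len_range,
    planted_features = planted, planted_weights = weights,
    noise_sd = noise_sd, rng_seed = seed)
  simulate_dataset(spec)
}
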