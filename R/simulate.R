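# Synthetic cohorts with planted, recoverable signal.
#
# The generator emulates the study conditions: a cohort of ~85 RNA-binding
# protein domains of realistic lengths (50-500 residues), per-residue
# structural profiles with label-consistent probability tracks, and
# activities built as a sparse linear function of a chosen subset of the
# encoded features plus Gaussian noise.  Everything is deterministic under
# (spec, seed).

#' Specify a synthetic cohort
#'
#' @param n_proteins Cohort size; default 85, the size of the experimental
#'   training set this generator emulates.
#' @param length_range Integer min/max sequence length, default c(50, 500).
#' @param planted_features Schema feature names carrying true signal.
#' @param planted_weights Linear weights, same length as
#'   `planted_features`, applied to the z-scored features.
#' @param noise_sd Gaussian noise standard deviation on the activity.
#' @param noise_relative If `TRUE`, `noise_sd` is interpreted as a multiple
#'   of the standard deviation of the noiseless planted signal.
#' @param rng_seed Integer seed; all three simulation stages derive their
#'   streams from it.
#' @param composition_bias Optional named letter->weight vector biasing
#'   residue sampling (uniform when `NULL`).
#' @param ss8_stay Persistence probability of the 8-state secondary
#'   structure Markov chain.
#' @param dirichlet_conc Dirichlet concentration on the drawn label for the
#'   probability tracks (1 on all other states).
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_proteins = 85,
                            length_range = c(50L, 500L),
                            planted_features = c(
                              "Dual-AAC_GT",
                              "Hydrophobicity_distribution_H-0.0",
                              "ASA-2th"),
                            planted_weights = c(1, 0.8, 0.6),
                            noise_sd = 0.15,
                            noise_relative = FALSE,
                            rng_seed = 1L,
                            composition_bias = NULL,
                            ss8_stay = 0.85,
                            dirichlet_conc = 20) {
  if (length(planted_features) != length(planted_weights)) {
    stop("planted_features and planted_weights must have equal length")
  }
  unknown <- setdiff(planted_features, feature_schema())
  if (length(unknown) > 0) {
    stop("unknown planted feature(s): ", paste(unknown, collapse = ", "),
         "; valid names come from feature_schema()")
  }
  if (length_range[1] < 2) stop("minimum length must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_proteins < 0) stop("n_proteins must be >= 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 planted_features = planted_features,
                 planted_weights = planted_weights,
                 noise_sd = noise_sd, noise_relative = noise_relative,
                 rng_seed = as.integer(rng_seed),
                 composition_bias = composition_bias,
                 ss8_stay = ss8_stay, dirichlet_conc = dirichlet_conc),
            class = "simulation_spec")
}

#' Simulate protein sequences
#'
#' Draws `n_proteins` sequences with lengths uniform over `length_range`
#' and residues i.i.d. per position (uniform over the 20 letters, or
#' weighted by `composition_bias`).  Activities are left unset.
#'
#' @param spec A [simulation_spec()].
#' @return data.frame with columns `id`, `sequence`, `activity` (all NA).
#' @export
simulate_proteins <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_proteins
  prob <- NULL
  letters_pool <- AA_ALPHABET
  if (!is.null(spec$composition_bias)) {
    bad <- setdiff(names(spec$composition_bias), AA_ALPHABET)
    if (length(bad) > 0) stop("composition_bias has non-canonical letters")
    prob <- rep(0, 20)
    names(prob) <- AA_ALPHABET
    prob[names(spec$composition_bias)] <- spec$composition_bias
    prob <- prob / sum(prob)
  }
  ids <- sprintf("RBP%03d", seq_len(n))
  lens <- if (n > 0) {
    sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
  } else integer(0)
  seqs <- vapply(lens, function(L) {
    paste(sample(letters_pool, L, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  data.frame(id = ids, sequence = seqs,
             activity = rep(NA_real_, n), stringsAsFactors = FALSE)
}

rdirichlet_on <- function(k, hot, conc) {
  alpha <- rep(1, k)
  alpha[hot] <- conc
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  g / sum(g)
}

# DSSP-like stationary frequencies of the 8 states used for jumps and the
# initial state of the persistent Markov chain.
SS8_BASE_FREQ <- c(G = 0.04, H = 0.30, I = 0.01, B = 0.02, E = 0.18,
                   S = 0.08, T = 0.10, C = 0.27)

#' Simulate structural profiles for a cohort
#'
#' Per residue, an 8-state secondary-structure label is drawn from a
#' persistent Markov chain (stay with probability `ss8_stay`, otherwise
#' jump to a state drawn from DSSP-like base frequencies); the 3-state
#' label is its condensation.  Probability tracks are Dirichlet draws
#' concentrated on the drawn label, ASA lies in [0, 250] square Angstroms,
#' exposure/contact counts are nonnegative, and backbone angles lie in
#' (-180, 180] degrees.
#'
#' @param proteins Cohort data.frame from [simulate_proteins()].
#' @param spec The same [simulation_spec()].
#' @return Named list of [structural_profile()] objects.
#' @export
simulate_profiles <- function(proteins, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed + 1L)
  profiles <- lapply(seq_len(nrow(proteins)), function(i) {
    aa <- strsplit(proteins$sequence[i], "")[[1]]
    L <- length(aa)
    ss8 <- character(L)
    state <- sample(SS8_STATES, 1, prob = SS8_BASE_FREQ)
    for (r in seq_len(L)) {
      ss8[r] <- state
      if (stats::runif(1) > spec$ss8_stay) {
        state <- sample(SS8_STATES, 1, prob = SS8_BASE_FREQ)
      }
    }
    ss3 <- condense_ss8(ss8)
    ss8_idx <- match(ss8, SS8_STATES)
    ss3_idx <- match(ss3, SS3_PROB_ORDER)
    ss8_probs <- t(vapply(ss8_idx, function(h) {
      rdirichlet_on(8, h, spec$dirichlet_conc)
    }, numeric(8)))
    ss3_probs <- t(vapply(ss3_idx, function(h) {
      rdirichlet_on(3, h, spec$dirichlet_conc)
    }, numeric(3)))
    wrap_angle <- function(x) ((x + 180) %% 360) - 180
    structural_profile(
      protein_id = proteins$id[i], aa = aa, ss8 = ss8,
      ss3_probs = ss3_probs, ss8_probs = ss8_probs,
      asa = 250 * stats::rbeta(L, 2, 3),
      hse_up = stats::rpois(L, 12),
      hse_down = stats::rpois(L, 15),
      cn = stats::rpois(L, 28),
      theta = wrap_angle(stats::rnorm(L, 100, 20)),
      tau = wrap_angle(stats::runif(L, -180, 180)),
      phi = wrap_angle(stats::rnorm(L, -70, 40)),
      psi = wrap_angle(stats::rnorm(L, 60, 80)))
  })
  stats::setNames(profiles, proteins$id)
}

#' Plant activities as a sparse linear function of encoded features
#'
#' Encodes the cohort, z-scores the planted feature columns across the
#' cohort, and sets each activity to the weighted sum of the planted
#' z-scores plus Gaussian noise:
#' `y_i = sum_k w_k z_k(i) + eps_i`, `eps ~ N(0, noise_sd^2)`.
#'
#' @param proteins Cohort data.frame.
#' @param profiles Matching structural profiles.
#' @param spec The [simulation_spec()] holding planted features, weights
#'   and noise level.
#' @return The cohort data.frame with `activity` filled in; the noiseless
#'   signal and the realized noise sd are attached as attributes
#'   `"signal"` and `"noise_sd"`.
#' @export
plant_activities <- function(proteins, profiles, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fm <- assemble_features(proteins, profiles)
  z <- fm$x[, spec$planted_features, drop = FALSE]
  sds <- apply(z, 2, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    stop("planted feature(s) constant across cohort: ",
         paste(spec$planted_features[flat], collapse = ", "))
  }
  z <- scale(z)
  signal <- as.vector(z %*% spec$planted_weights)
  noise_sd <- if (spec$noise_relative) {
    spec$noise_sd * stats::sd(signal)
  } else {
    spec$noise_sd
  }
  set.seed(spec$rng_seed + 2L)
  proteins$activity <- signal + stats::rnorm(length(signal), 0, noise_sd)
  attr(proteins, "signal") <- signal
  attr(proteins, "noise_sd") <- noise_sd
  proteins
}

#' Simulate a full labelled cohort
#'
#' Convenience wrapper chaining [simulate_proteins()],
#' [simulate_profiles()] and [plant_activities()].
#'
#' @param spec A [simulation_spec()].
#' @return List with `proteins` (activities set), `profiles`, and `truth`
#'   (planted features, weights, realized noise sd).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  proteins <- simulate_proteins(spec)
  profiles <- simulate_profiles(proteins, spec)
  proteins <- plant_activities(proteins, profiles, spec)
  list(proteins = proteins, profiles = profiles,
       truth = list(planted_features = spec$planted_features,
                    planted_weights = spec$planted_weights,
                    noise_sd = attr(proteins, "noise_sd"),
                    rng_seed = spec$rng_seed))
}

#' Simulate a latent-factor regression design
#'
#' A direct generator for sanity-checking the latent-component regression:
#' `X = T P' + E` with `n_factors` latent factors of staggered variance and
#' `y` the equally-weighted sum of the (standardized) factors plus noise.
#' A component sweep on such data should peak near `n_factors` components.
#'
#' @param n Samples. @param p Features. @param n_factors Latent factors.
#' @param x_noise_sd Feature noise sd. @param y_noise_sd Response noise sd
#'   (relative to sd of the noiseless response).
#' @param seed Integer seed.
#' @return List with matrix `x` and vector `y`.
#' @export
simulate_latent_design <- function(n = 100, p = 40, n_factors = 3,
                                   x_noise_sd = 0.5, y_noise_sd = 0.3,
                                   seed = 1) {
  set.seed(seed)
  scores <- matrix(stats::rnorm(n * n_factors), n, n_factors)
  scores <- sweep(scores, 2, seq(n_factors, 1), "*")
  loadings <- matrix(stats::rnorm(p * n_factors), p, n_factors)
  x <- scores %*% t(loadings) +
    matrix(stats::rnorm(n * p, 0, x_noise_sd), n, p)
  colnames(x) <- sprintf("F%03d", seq_len(p))
  rownames(x) <- sprintf("S%03d", seq_len(n))
  y0 <- rowSums(scale(scores))
  y <- y0 + stats::rnorm(n, 0, y_noise_sd * stats::sd(y0))
  list(x = x, y = y)
}
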