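# Structure-derived descriptors from per-residue profiles: SS3/SS8
# pseudosequence features plus three-part means of probability and
# continuous tracks.

#' Pseudosequence features over a secondary-structure alphabet
#'
#' Composition (state frequencies), dual composition (ordered adjacent-pair
#' frequencies, denominator = total pair count) and five-anchor
#' distribution features of a label sequence.  For the 3-state alphabet
#' this yields 3 + 9 + 15 = 27 features; for the 8-state alphabet
#' 8 + 64 + 40 = 112.
#'
#' @param labels Character vector of per-residue state labels.
#' @param states State alphabet, e.g. `c("H","E","C")` for SS3.
#' @param prefix Feature-name prefix (`"SS3"` or `"SS8"`).
#' @return Named numeric vector of `k + k^2 + 5k` features for `k` states.
#' @export
pseudoseq_features <- function(labels, states, prefix) {
  if (length(labels) < 2) stop("pseudosequence length must be >= 2")
  bad <- !labels %in% states
  if (any(bad)) {
    stop("label '", labels[which(bad)[1]], "' outside state alphabet {",
         paste(states, collapse = ","), "}")
  }
  comp <- stats::setNames(state_composition(labels, states),
                          paste0(prefix, "_composition_", states))
  k <- length(states)
  dual <- stats::setNames(
    state_dual_composition(labels, states),
    paste0(prefix, "_Dual_", rep(states, each = k), rep(states, k)))
  dist <- stats::setNames(state_distribution(labels, states),
                          dist_feature_names(prefix, states))
  c(comp, dual, dist)
}

#' Three-part means of a numeric track
#'
#' Divides a length-L track into first, middle and end parts with
#' boundaries at `floor(L/3)` and `floor(2L/3)` and returns the arithmetic
#' mean of each part.
#'
#' @param track Numeric vector, length >= 3.
#' @return Numeric vector of 3 part means.
#' @export
#' @examples
#' three_part_means(1:7)  # parts {1,2}, {3,4}, {5,6,7}
three_part_means <- function(track) {
  L <- length(track)
  if (L < 3) stop("three-part means require length >= 3")
  b1 <- floor(L / 3)
  b2 <- floor(2 * L / 3)
  c(mean(track[1:b1]), mean(track[(b1 + 1):b2]), mean(track[(b2 + 1):L]))
}

#' Full structural encoding of a profile
#'
#' Concatenates: SS3 pseudosequence features (27) and three-part means of
#' the three SS3 class-probability tracks (9), totalling 36; SS8
#' pseudosequence features (112) plus 8 x 3 probability part-means (24),
#' totalling 136; and three-part means of the eight remaining tracks
#' (ASA, HSE up/down, contact number, backbone angles theta/tau/phi/psi),
#' 24 features.  Grand total 196, of which the SS3 + SS8 block is 172.
#'
#' @param profile A [structural_profile()] of length >= 3.
#' @return Named numeric vector of 196 features.
#' @export
encode_structure <- function(profile) {
  L <- length(profile$aa)
  if (L < 3) {
    stop("profile '", profile$protein_id,
         "': structural encoding requires length >= 3")
  }
  ss3_part <- unlist(lapply(SS3_PROB_ORDER, function(s) {
    stats::setNames(three_part_means(profile$ss3_probs[, s]),
                    paste0("SS3_prob_", s, "-", 1:3, "th"))
  }))
  ss8_part <- unlist(lapply(SS8_STATES, function(s) {
    stats::setNames(three_part_means(profile$ss8_probs[, s]),
                    paste0("SS8_prob_", s, "-", 1:3, "th"))
  }))
  other <- unlist(lapply(OTHER_TRACKS, function(tr) {
    stats::setNames(three_part_means(profile[[tr]]),
                    paste0(OTHER_TRACK_LABELS[[tr]], "-", 1:3, "th"))
  }))
  c(pseudoseq_features(profile$ss3, SS3_STATES, "SS3"), ss3_part,
    pseudoseq_features(profile$ss8, SS8_STATES, "SS8"), ss8_part,
    other)
}
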