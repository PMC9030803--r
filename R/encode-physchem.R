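# CTD (composition-transition-distribution) physicochemical descriptors.
#
# Each of four properties (hydrophobicity, normalized Van der Waals volume,
# polarity, polarizability) recodes the sequence into a three-symbol
# pseudosequence (tags P/N/H) and contributes 21 features: 3 composition,
# 3 transition and 15 distribution values.

#' Recode a protein sequence into a three-group pseudosequence
#'
#' Replaces each residue by the tag (P, N or H) of the physicochemical
#' group it belongs to under the given property grouping.
#'
#' @param sequence Protein sequence string.
#' @param grouping One element of [ctd_groupings()].
#' @return String of the same length over the alphabet P/N/H.
#' @export
#' @examples
#' to_pseudosequence("RKED", ctd_groupings()$Hydrophobicity)
to_pseudosequence <- function(sequence, grouping) {
  lut <- character(0)
  for (sym in names(grouping$groups)) {
    lut[grouping$groups[[sym]]] <- sym
  }
  chars <- strsplit(sequence, "")[[1]]
  paste(lut[chars], collapse = "")
}

#' CTD composition features of a pseudosequence
#'
#' Occurrence frequencies of the three group symbols in the whole
#' pseudosequence.
#'
#' @param pseudo Pseudosequence string over P/N/H.
#' @param property Property name used as the feature-name prefix.
#' @return Named numeric vector of 3 features summing to 1.
#' @export
ctd_composition <- function(pseudo, property = "Property") {
  if (nchar(pseudo) < 1) stop("empty pseudosequence")
  chars <- strsplit(pseudo, "")[[1]]
  stats::setNames(state_composition(chars, c("P", "N", "H")),
                  paste0(property, "_composition_", c("P", "N", "H")))
}

#' CTD transition features of a pseudosequence
#'
#' For each unordered pair of distinct group symbols, the frequency of
#' adjacent positions where the symbol changes between the two (counting
#' both directions), divided by the total number of adjacent pairs
#' (length - 1).
#'
#' @inheritParams ctd_composition
#' @return Named numeric vector of 3 features (pairs PN, PH, NH).
#' @export
ctd_transition <- function(pseudo, property = "Property") {
  L <- nchar(pseudo)
  if (L < 2) stop("transition features require length >= 2")
  chars <- strsplit(pseudo, "")[[1]]
  a <- chars[-L]
  b <- chars[-1]
  pair_count <- function(x, y) sum((a == x & b == y) | (a == y & b == x))
  vals <- c(pair_count("P", "N"), pair_count("P", "H"),
            pair_count("N", "H")) / (L - 1)
  stats::setNames(vals, paste0(property, "_transition_",
                               c("PN", "PH", "NH")))
}

#' CTD distribution features of a pseudosequence
#'
#' For each group symbol, five values: the relative sequence position (per
#' unit length) of the first occurrence and of the occurrences at the 25,
#' 50, 75 and 100% occurrence quantiles (occurrence index
#' `max(1, ceiling(q * n_g))`).  All five are 0 when the symbol is absent.
#'
#' @inheritParams ctd_composition
#' @return Named numeric vector of 15 features, each in [0, 1].
#' @export
ctd_distribution <- function(pseudo, property = "Property") {
  if (nchar(pseudo) < 1) stop("empty pseudosequence")
  chars <- strsplit(pseudo, "")[[1]]
  stats::setNames(state_distribution(chars, c("P", "N", "H")),
                  dist_feature_names(property, c("P", "N", "H")))
}

#' Full physicochemical CTD encoding of a protein sequence
#'
#' Concatenates the 21 CTD features (3 composition + 3 transition + 15
#' distribution) for each of the four properties: 84 features in total.
#'
#' @param sequence Protein sequence string, length >= 2.
#' @param groupings Property groupings, default [ctd_groupings()].
#' @return Named numeric vector of 84 features.
#' @export
encode_physchem <- function(sequence, groupings = ctd_groupings()) {
  if (nchar(sequence) < 2) {
    stop("physicochemical encoding requires sequence length >= 2")
  }
  out <- lapply(groupings, function(g) {
    pseudo <- to_pseudosequence(sequence, g)
    c(ctd_composition(pseudo, g$property),
      ctd_transition(pseudo, g$property),
      ctd_distribution(pseudo, g$property))
  })
  unlist(unname(out))
}
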