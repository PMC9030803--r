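# Sequence-composition encoders: AAC and Dual-AAC (dipeptide composition).

# Shared helpers over an arbitrary state alphabet ------------------------

state_composition <- function(chars, states) {
  counts <- table(factor(chars, levels = states))
  as.vector(counts) / length(chars)
}

# Ordered adjacent-pair frequencies, denominator = total pair count (L-1).
state_dual_composition <- function(chars, states) {
  L <- length(chars)
  pairs <- paste0(chars[-L], chars[-1])
  lv <- paste0(rep(states, each = length(states)), rep(states,
                                                       length(states)))
  counts <- table(factor(pairs, levels = lv))
  as.vector(counts) / (L - 1)
}

# Five-anchor distribution descriptor per state: relative position of the
# first occurrence and of the 25/50/75/100% occurrence quantiles
# (occurrence index max(1, ceiling(q * n_g))); all zero when absent.
state_distribution <- function(chars, states) {
  L <- length(chars)
  out <- numeric(5 * length(states))
  for (k in seq_along(states)) {
    pos <- which(chars == states[k])
    n_g <- length(pos)
    if (n_g > 0) {
      idx <- pmax(1, ceiling(DIST_ANCHOR_Q * n_g))
      out[(k - 1) * 5 + 1:5] <- pos[idx] / L
    }
  }
  out
}

# ------------------------------------------------------------------------

#' Amino-acid composition (AAC)
#'
#' Frequency of each of the 20 canonical amino acids in the sequence:
#' `p_i = c_i / len(seq)`.
#'
#' @param sequence Protein sequence string over the canonical alphabet.
#' @return Named numeric vector of 20 features (`AAC_A` ... `AAC_Y`),
#'   summing to 1.
#' @export
#' @examples
#' encode_aac("AAC")
encode_aac <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      nchar(sequence) < 1) {
    stop("sequence must be a non-empty string")
  }
  chars <- strsplit(sequence, "")[[1]]
  validate_sequence("<sequence>", paste(chars, collapse = ""))
  stats::setNames(state_composition(chars, AA_ALPHABET),
                  paste0("AAC_", AA_ALPHABET))
}

#' Dual amino-acid composition (dipeptide composition)
#'
#' Frequency of each ordered adjacent amino-acid pair:
#' `D_ij = f_ij / (len(seq) - 1)`, where `f_ij` counts transitions from
#' residue type i to type j.  Equivalent to the composition of 0-spaced
#' amino-acid pairs (CKSAAP with K = 0).
#'
#' @param sequence Protein sequence string, length >= 2.
#' @return Named numeric vector of 400 features (`Dual-AAC_AA` ...
#'   `Dual-AAC_YY`), summing to 1.
#' @export
#' @examples
#' encode_dual_aac("ACAC")
encode_dual_aac <- function(sequence) {
  if (nchar(sequence) < 2) {
    stop("Dual-AAC requires sequence length >= 2")
  }
  chars <- strsplit(sequence, "")[[1]]
  validate_sequence("<sequence>", sequence)
  nm <- paste0("Dual-AAC_", rep(AA_ALPHABET, each = 20),
               rep(AA_ALPHABET, 20))
  stats::setNames(state_dual_composition(chars, AA_ALPHABET), nm)
}
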