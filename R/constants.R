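# Alphabets, state spaces and the fixed 700-feature schema.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Three-state secondary-structure alphabet (helix, strand, coil)
#' @keywords internal
SS3_STATES <- c("H", "E", "C")

#' Eight-state (DSSP-style) secondary-structure alphabet
#' @keywords internal
SS8_STATES <- c("G", "H", "I", "B", "E", "S", "T", "C")

# 8-state -> 3-state condensation: 310/alpha/pi helices -> H,
# beta bridge/strand -> E, everything else -> C.
SS8_TO_SS3 <- c(G = "H", H = "H", I = "H", B = "E", E = "E",
                S = "C", T = "C", C = "C")

# Distribution descriptors use five anchors: the first occurrence ("0.0")
# plus the 25/50/75/100% occurrence quantiles.
DIST_ANCHOR_Q <- c(0, 0.25, 0.5, 0.75, 1)
DIST_ANCHOR_TAG <- c("0.0", "0.25", "0.5", "0.75", "1.0")

# Continuous per-residue structural tracks summarised by three-part means.
OTHER_TRACKS <- c("asa", "hse_up", "hse_down", "cn",
                  "theta", "tau", "phi", "psi")
OTHER_TRACK_LABELS <- c(
  asa = "ASA", hse_up = "HSE_up", hse_down = "HSE_down", cn = "CN",
  theta = "Backbone angle_theta", tau = "Backbone angle_tau",
  phi = "Backbone angle_phi", psi = "Backbone angle_psi")

#' Condense 8-state secondary-structure labels to 3 states
#'
#' Maps DSSP-style 8-state labels to the 3-state alphabet: G/H/I (helices)
#' to H, B/E (strands) to E, and S/T/C (everything else) to C.
#'
#' @param ss8 Character vector of single-letter 8-state labels.
#' @return Character vector of 3-state labels (H, E or C).
#' @export
#' @examples
#' condense_ss8(c("G", "E", "T"))
condense_ss8 <- function(ss8) {
  bad <- !ss8 %in% SS8_STATES
  if (any(bad)) {
    stop("invalid SS8 label(s): ", paste(unique(ss8[bad]), collapse = ", "))
  }
  unname(SS8_TO_SS3[ss8])
}

#' Physicochemical three-group classifications for CTD descriptors
#'
#' Returns the three-group amino-acid classifications used by the
#' composition-transition-distribution (CTD) encoder, one per property:
#' hydrophobicity, normalized Van der Waals volume, polarity and
#' polarizability.  These are the canonical Dubchak-style groupings from the
#' CTD literature.  Within each property the three groups are tagged P, N
#' and H (for hydrophobicity these read naturally as polar / neutral /
#' hydrophobic; for the other properties they are simply the group-1/2/3
#' tags).
#'
#' @param path Optional path to a grouping table TSV with columns
#'   `property`, `symbol`, `letters` overriding the built-in tables.
#' @return Named list of property groupings; each element is a list with
#'   `property` and `groups` (a named list of letter vectors, names P/N/H).
#' @export
ctd_groupings <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_grouping_table(path))
  }
  split_letters <- function(x) strsplit(x, "")[[1]]
  make <- function(property, p, n, h) {
    g <- list(P = split_letters(p), N = split_letters(n),
              H = split_letters(h))
    validate_grouping(property, g)
    list(property = property, groups = g)
  }
  list(
    Hydrophobicity = make("Hydrophobicity", "RKEDQN", "GASTPHY", "CLVIMFW"),
    VDWVolume      = make("VDWVolume",      "GASTPDC", "NVEQIL", "MHKFRYW"),
    Polarity       = make("Polarity",       "LIFWCMVY", "PATGS", "HQRKNED"),
    Polarizability = make("Polarizability", "GASDT", "CPNVEQIL", "KMHFRYW")
  )
}

validate_grouping <- function(property, groups) {
  all_letters <- sort(unlist(groups, use.names = FALSE))
  if (!identical(all_letters, sort(AA_ALPHABET))) {
    stop("grouping for ", property,
         " does not partition the 20-letter alphabet")
  }
  invisible(TRUE)
}

#' Read a CTD grouping table
#'
#' @param path TSV with columns `property`, `symbol` (P/N/H), `letters`.
#' @return Named list in the same shape as [ctd_groupings()].
#' @export
read_grouping_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("property", "symbol", "letters")
  if (!all(need %in% names(tab))) {
    stop("grouping table must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (prop in unique(tab$property)) {
    sub <- tab[tab$property == prop, ]
    groups <- stats::setNames(
      lapply(sub$letters, function(x) strsplit(x, "")[[1]]), sub$symbol)
    groups <- groups[c("P", "N", "H")]
    validate_grouping(prop, groups)
    out[[prop]] <- list(property = prop, groups = groups)
  }
  out
}

dist_feature_names <- function(prefix, symbols) {
  as.vector(vapply(symbols, function(s) {
    paste0(prefix, "_distribution_", s, "-", DIST_ANCHOR_TAG)
  }, character(5)))
}

#' The fixed 700-feature schema
#'
#' Returns the ordered names of the full protein encoding: 20 amino-acid
#' composition (AAC) features, 400 dipeptide (Dual-AAC) features, 84
#' physicochemical CTD features (21 per property over four properties),
#' 36 SS3-derived features, 136 SS8-derived features, and 24 three-part
#' means of the remaining structural tracks (ASA, HSE up/down, contact
#' number and the four backbone angles).
#'
#' @return Character vector of length 700.
#' @export
#' @examples
#' length(feature_schema())
feature_schema <- function() {
  if (is.null(.schema_cache$names)) {
    aac <- paste0("AAC_", AA_ALPHABET)
    dual <- paste0("Dual-AAC_",
                   rep(AA_ALPHABET, each = 20), rep(AA_ALPHABET, 20))
    phys <- unlist(lapply(names(ctd_groupings()), function(prop) {
      c(paste0(prop, "_composition_", c("P", "N", "H")),
        paste0(prop, "_transition_", c("PN", "PH", "NH")),
        dist_feature_names(prop, c("P", "N", "H")))
    }), use.names = FALSE)
    ss3 <- c(pseudoseq_feature_names("SS3", SS3_STATES),
             paste0("SS3_prob_", rep(c("C", "E", "H"), each = 3),
                    "-", rep(1:3, 3), "th"))
    ss8 <- c(pseudoseq_feature_names("SS8", SS8_STATES),
             paste0("SS8_prob_", rep(SS8_STATES, each = 3),
                    "-", rep(1:3, 8), "th"))
    other <- paste0(rep(OTHER_TRACK_LABELS, each = 3),
                    "-", rep(1:3, 8), "th")
    .schema_cache$names <- c(aac, dual, phys, ss3, ss8, other)
    stopifnot(length(.schema_cache$names) == 700L,
              !anyDuplicated(.schema_cache$names))
  }
  .schema_cache$names
}

.schema_cache <- new.env(parent = emptyenv())

pseudoseq_feature_names <- function(prefix, states) {
  k <- length(states)
  c(paste0(prefix, "_composition_", states),
    paste0(prefix, "_Dual_", rep(states, each = k), rep(states, k)),
    dist_feature_names(prefix, states))
}

#' Classify feature names into descriptor families
#'
#' Assigns each feature of the 700-feature schema to one of three families:
#' sequence composition (AAC and Dual-AAC), physicochemical (CTD), or
#' structural (SS3/SS8 and track summaries).  Used for the per-family
#' importance decomposition of a selected feature subset.
#'
#' @param feature_names Character vector of schema feature names.
#' @return Factor with levels `sequence`, `physicochemical`, `structural`.
#' @export
feature_family <- function(feature_names) {
  props <- names(ctd_groupings())
  fam <- ifelse(
    grepl("^(AAC_|Dual-AAC_)", feature_names), "sequence",
    ifelse(grepl(paste0("^(", paste(props, collapse = "|"), ")_"),
                 feature_names), "physicochemical", "structural"))
  unknown <- !feature_names %in% feature_schema()
  if (any(unknown)) {
    stop("unknown feature name(s): ",
         paste(utils::head(feature_names[unknown], 5), collapse = ", "))
  }
  factor(fam, levels = c("sequence", "physicochemical", "structural"))
}
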