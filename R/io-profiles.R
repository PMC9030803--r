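# Per-residue structural profiles in a structure-predictor-style TSV dialect.
#
# One file per protein (<protein_id>.tsv).  Columns, in order:
#   idx aa ss3 ss8 asa hse_up hse_down cn theta tau phi psi
#   p_C p_E p_H            (3-state probabilities, order C/E/H)
#   p_G p_H8 p_I p_B p_E8 p_S p_T p_C8   (8-state probabilities)
# idx is 1-based in files; internal storage is plain vectors/matrices.

PROFILE_COLUMNS <- c("idx", "aa", "ss3", "ss8", "asa", "hse_up", "hse_down",
                     "cn", "theta", "tau", "phi", "psi",
                     "p_C", "p_E", "p_H",
                     "p_G", "p_H8", "p_I", "p_B", "p_E8", "p_S", "p_T",
                     "p_C8")
SS3_PROB_ORDER <- c("C", "E", "H")

#' Construct a per-residue structural profile
#'
#' Bundles the one-dimensional structural tracks of a protein as produced by
#' a secondary-structure predictor: 3- and 8-state secondary-structure
#' labels and class probabilities, solvent accessible surface area (ASA,
#' square Angstroms), half-sphere exposure up/down counts, contact number,
#' and the four backbone angles theta, tau, phi, psi (degrees).
#'
#' The 3-state label must equal the condensation of the 8-state label at
#' every residue, and each probability row must be nonnegative and sum to
#' 1 within 1e-3.
#'
#' @param protein_id Protein identifier.
#' @param aa Character vector of residues.
#' @param ss8 Character vector of 8-state labels (G,H,I,B,E,S,T,C).
#' @param ss3_probs L x 3 matrix, columns in order C, E, H.
#' @param ss8_probs L x 8 matrix, columns in order G,H,I,B,E,S,T,C.
#' @param asa,hse_up,hse_down,cn,theta,tau,phi,psi Numeric tracks, length L.
#' @param ss3 Optional 3-state labels; derived from `ss8` when omitted,
#'   validated against the condensation rule when given.
#' @return An object of class `structural_profile`.
#' @export
structural_profile <- function(protein_id, aa, ss8, ss3_probs, ss8_probs,
                               asa, hse_up, hse_down, cn,
                               theta, tau, phi, psi, ss3 = NULL) {
  L <- length(aa)
  expected <- condense_ss8(ss8)
  if (!is.null(ss3)) ss3 <- unname(ss3)
  if (is.null(ss3)) {
    ss3 <- expected
  } else if (!identical(ss3, expected)) {
    i <- which(ss3 != expected)[1]
    stop("profile '", protein_id, "' row ", i, ": ss3 label '", ss3[i],
         "' inconsistent with ss8 '", ss8[i], "' (condenses to '",
         expected[i], "')")
  }
  ss3_probs <- as.matrix(ss3_probs)
  ss8_probs <- as.matrix(ss8_probs)
  dimnames(ss3_probs) <- list(NULL, SS3_PROB_ORDER)
  dimnames(ss8_probs) <- list(NULL, SS8_STATES)
  aa <- unname(aa)
  ss8 <- unname(ss8)
  tracks <- list(asa = asa, hse_up = hse_up, hse_down = hse_down, cn = cn,
                 theta = theta, tau = tau, phi = phi, psi = psi)
  lens <- c(length(ss8), nrow(ss3_probs), nrow(ss8_probs),
            vapply(tracks, length, integer(1)))
  if (any(lens != L)) {
    stop("profile '", protein_id, "': track lengths differ from ", L)
  }
  check_simplex(ss3_probs, protein_id, "ss3")
  check_simplex(ss8_probs, protein_id, "ss8")
  structure(
    c(list(protein_id = protein_id, aa = aa, ss3 = ss3, ss8 = ss8,
           ss3_probs = ss3_probs, ss8_probs = ss8_probs), tracks),
    class = "structural_profile")
}

check_simplex <- function(probs, protein_id, what) {
  if (any(probs < 0)) {
    i <- which(apply(probs, 1, function(r) any(r < 0)))[1]
    stop("profile '", protein_id, "' row ", i, ": negative ", what,
         " probability")
  }
  s <- rowSums(probs)
  off <- which(abs(s - 1) > 1e-3)
  if (length(off) > 0) {
    stop("profile '", protein_id, "' row ", off[1], ": ", what,
         " probabilities sum to ", format(s[off[1]]), ", expected 1")
  }
  invisible(TRUE)
}

#' @export
print.structural_profile <- function(x, ...) {
  cat("<structural_profile> ", x$protein_id, ": ", length(x$aa),
      " residues\n", sep = "")
  invisible(x)
}

#' @export
length.structural_profile <- function(x) length(x$aa)

#' Read one structural profile from its TSV file
#'
#' @param path Path to a `<protein_id>.tsv` profile file.
#' @param protein_id Identifier; defaults to the file name without
#'   extension.
#' @param column_map Optional named character vector remapping this
#'   package's canonical column names to the names present in the file
#'   (an adapter for real predictor outputs).
#' @return A [structural_profile()] object.
#' @export
read_structural_profile <- function(path, protein_id = NULL,
                                    column_map = NULL) {
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  # aa/ss3/ss8 columns of all "T" must not stay parsed as logicals
  for (col in intersect(c("aa", "ss3", "ss8"), names(tab))) {
    if (is.logical(tab[[col]])) {
      tab[[col]] <- ifelse(tab[[col]], "T", "F")
    }
    tab[[col]] <- as.character(tab[[col]])
  }
  if (!is.null(column_map)) {
    hit <- match(column_map, names(tab))
    if (anyNA(hit)) stop("column_map names absent from ", path)
    names(tab)[hit] <- names(column_map)
  }
  missing <- setdiff(PROFILE_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("profile file ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[order(tab$idx), ]
  structural_profile(
    protein_id = protein_id,
    aa = tab$aa, ss3 = tab$ss3, ss8 = tab$ss8,
    ss3_probs = as.matrix(tab[, c("p_C", "p_E", "p_H")]),
    ss8_probs = as.matrix(tab[, c("p_G", "p_H8", "p_I", "p_B",
                                  "p_E8", "p_S", "p_T", "p_C8")]),
    asa = tab$asa, hse_up = tab$hse_up, hse_down = tab$hse_down,
    cn = tab$cn, theta = tab$theta, tau = tab$tau, phi = tab$phi,
    psi = tab$psi)
}

#' Write a structural profile to TSV
#'
#' @param profile A [structural_profile()].
#' @param path Output path.
#' @export
write_structural_profile <- function(profile, path) {
  L <- length(profile$aa)
  num <- function(x) sprintf("%.12g", x)
  tab <- data.frame(
    idx = seq_len(L), aa = profile$aa, ss3 = profile$ss3,
    ss8 = profile$ss8,
    asa = num(profile$asa), hse_up = num(profile$hse_up),
    hse_down = num(profile$hse_down), cn = num(profile$cn),
    theta = num(profile$theta), tau = num(profile$tau),
    phi = num(profile$phi), psi = num(profile$psi),
    p_C = num(profile$ss3_probs[, "C"]),
    p_E = num(profile$ss3_probs[, "E"]),
    p_H = num(profile$ss3_probs[, "H"]),
    p_G = num(profile$ss8_probs[, "G"]),
    p_H8 = num(profile$ss8_probs[, "H"]),
    p_I = num(profile$ss8_probs[, "I"]),
    p_B = num(profile$ss8_probs[, "B"]),
    p_E8 = num(profile$ss8_probs[, "E"]),
    p_S = num(profile$ss8_probs[, "S"]),
    p_T = num(profile$ss8_probs[, "T"]),
    p_C8 = num(profile$ss8_probs[, "C"]),
    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read all structural profiles from a directory
#'
#' Expects one `<protein_id>.tsv` per protein.
#'
#' @param dir Directory of profile TSV files.
#' @param ids Optional character vector restricting (and ordering) which
#'   profiles to read; an id without a file is an error.
#' @param column_map Passed to [read_structural_profile()].
#' @return Named list of [structural_profile()] objects.
#' @export
read_profiles <- function(dir, ids = NULL, column_map = NULL) {
  if (is.null(ids)) {
    files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
    ids <- sub("\\.tsv$", "", basename(files))
  } else {
    files <- file.path(dir, paste0(ids, ".tsv"))
    absent <- !file.exists(files)
    if (any(absent)) {
      stop("no profile file for protein(s): ",
           paste(ids[absent], collapse = ", "))
    }
  }
  profiles <- lapply(seq_along(files), function(i) {
    read_structural_profile(files[i], protein_id = ids[i],
                            column_map = column_map)
  })
  stats::setNames(profiles, ids)
}

#' Write structural profiles to a directory
#'
#' @param profiles Named list of [structural_profile()] objects.
#' @param dir Output directory (created if absent).
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in profiles) {
    write_structural_profile(p, file.path(dir, paste0(p$protein_id,
                                                      ".tsv")))
  }
  invisible(dir)
}
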