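# The cohort feature matrix: assembly, near-zero filtering, z-scoring.

new_feature_matrix <- function(x, normalized = FALSE, center = NULL,
                               scale = NULL, dropped = character(0)) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  if (anyNA(x)) stop("feature matrix contains NA/NaN")
  structure(list(x = x, normalized = normalized, center = center,
                 scale = scale, dropped = dropped),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$x), " proteins x ", ncol(x$x),
      " features", if (x$normalized) " (z-scored)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @method as.matrix feature_matrix
#' @export
as.matrix.feature_matrix <- function(x, ...) x$x

#' Assemble the 700-feature matrix for a protein cohort
#'
#' Encodes every protein with the four encoder families (AAC, Dual-AAC,
#' physicochemical CTD, structural) and stacks the vectors into a matrix
#' with one row per protein, columns in the fixed [feature_schema()] order.
#'
#' @param proteins data.frame with columns `id`, `sequence` (and
#'   optionally `activity`), as from [read_proteins()].
#' @param profiles Named list of [structural_profile()] objects; every
#'   protein id must have a profile whose length matches its sequence.
#' @param groupings CTD property groupings, default [ctd_groupings()].
#' @return A `feature_matrix` (un-normalized) with 700 columns.
#' @export
assemble_features <- function(proteins, profiles,
                              groupings = ctd_groupings()) {
  schema <- feature_schema()
  x <- matrix(NA_real_, nrow = nrow(proteins), ncol = length(schema),
              dimnames = list(proteins$id, schema))
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$id[i]
    prof <- profiles[[id]]
    if (is.null(prof)) stop("no structural profile for protein '", id, "'")
    seq <- proteins$sequence[i]
    if (length(prof$aa) != nchar(seq)) {
      stop("protein '", id, "': profile has ", length(prof$aa),
           " rows but sequence has ", nchar(seq), " residues")
    }
    v <- c(encode_aac(seq), encode_dual_aac(seq),
           encode_physchem(seq, groupings), encode_structure(prof))
    if (!identical(names(v), schema)) {
      stop("internal error: encoder output does not match schema")
    }
    x[i, ] <- v
  }
  new_feature_matrix(x)
}

#' Drop near-zero (and constant) features
#'
#' Removes every column whose maximum absolute value across the cohort is
#' strictly below `epsilon`.  With `drop_constant = TRUE` (default),
#' zero-variance columns are removed as well, since they carry no
#' information and break z-scoring.
#'
#' @param fm A `feature_matrix` (un-normalized).
#' @param epsilon Near-zero threshold, default `1e-8`.
#' @param drop_constant Also drop constant columns.
#' @return A `feature_matrix` with surviving columns in original order;
#'   removed names are recorded in `$dropped`.
#' @export
drop_near_zero <- function(fm, epsilon = 1e-8, drop_constant = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (fm$normalized) stop("drop_near_zero expects an un-normalized matrix")
  max_abs <- apply(abs(fm$x), 2, max)
  drop <- max_abs < epsilon
  if (drop_constant) {
    sds <- apply(fm$x, 2, stats::sd)
    drop <- drop | sds == 0
  }
  new_feature_matrix(fm$x[, !drop, drop = FALSE],
                     dropped = c(fm$dropped, colnames(fm$x)[drop]))
}

#' Z-score normalize a feature matrix
#'
#' Centers each column to mean 0 and scales to standard deviation 1
#' (sample sd, denominator n - 1): `X' = (X - X_mean) / X_std`.  The
#' centering and scaling vectors are stored so the transform can be
#' inverted exactly.
#'
#' @param fm A `feature_matrix` with no constant columns (run
#'   [drop_near_zero()] first).
#' @return A normalized `feature_matrix`.
#' @export
zscore_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  ctr <- colMeans(fm$x)
  sds <- apply(fm$x, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    stop("zero-variance feature(s): ",
         paste(utils::head(colnames(fm$x)[zero], 5), collapse = ", "),
         " - drop them before z-scoring")
  }
  z <- sweep(sweep(fm$x, 2, ctr), 2, sds, "/")
  new_feature_matrix(z, normalized = TRUE, center = ctr, scale = sds,
                     dropped = fm$dropped)
}

#' Invert the z-score transform
#'
#' @param fm A normalized `feature_matrix` from [zscore_features()].
#' @return The un-normalized `feature_matrix`.
#' @export
inverse_zscore <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"), fm$normalized)
  x <- sweep(sweep(fm$x, 2, fm$scale, "*"), 2, fm$center, "+")
  new_feature_matrix(x, dropped = fm$dropped)
}

#' Write a feature matrix to TSV
#'
#' @param fm A `feature_matrix`.
#' @param path Output path; header = feature names, first column = id.
#' @export
write_feature_matrix <- function(fm, path) {
  tab <- data.frame(id = rownames(fm$x), fm$x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @param normalized Whether the stored values are z-scored.
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path, normalized = FALSE) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- tab[[1]]
  new_feature_matrix(x, normalized = normalized)
}
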