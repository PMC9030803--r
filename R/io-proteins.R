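# Reading and writing protein cohorts: FASTA sequences + activity tables.

validate_sequence <- function(id, sequence) {
  if (nchar(sequence) < 2) {
    stop("protein '", id, "': sequence length must be >= 2")
  }
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop("protein '", id, "': non-canonical residue '", chars[bad[1]],
         "' at position ", bad[1])
  }
  invisible(TRUE)
}

#' Read a protein cohort from FASTA, optionally attaching activities
#'
#' Reads amino-acid sequences from a FASTA file and, if given, attaches
#' per-protein activity labels (log10 fold change in splicing activity)
#' from a two-column TSV.  Sequences are validated against the 20-letter
#' canonical alphabet.
#'
#' @param fasta_path Path to a FASTA file (wrapped or single-line).
#' @param activity_path Optional path to a TSV with header `id<TAB>activity`.
#'   Every id in the table must be present in the FASTA.
#' @return A data.frame with columns `id`, `sequence`, `activity`
#'   (`NA` where no label was supplied), in FASTA order.
#' @export
read_proteins <- function(fasta_path, activity_path = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- as.character(seqs)
  for (i in seq_along(ids)) validate_sequence(ids[i], sequences[i])
  proteins <- data.frame(id = ids, sequence = unname(sequences),
                         activity = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(activity_path)) {
    act <- read_activities(activity_path)
    missing <- setdiff(act$id, proteins$id)
    if (length(missing) > 0) {
      stop("activity table ids absent from FASTA: ",
           paste(missing, collapse = ", "))
    }
    proteins$activity <- act$activity[match(proteins$id, act$id)]
  }
  proteins
}

#' Read an activity table
#'
#' @param path TSV with header columns `id` and `activity`.
#' @return data.frame with columns `id`, `activity`.
#' @export
read_activities <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "activity") %in% names(tab))) {
    stop("activity table must have columns 'id' and 'activity'")
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate ids in activity table")
  }
  tab$activity <- as.numeric(tab$activity)
  if (anyNA(tab$activity)) stop("non-numeric activity value in ", path)
  tab[, c("id", "activity")]
}

#' Write a protein cohort to FASTA
#'
#' @param proteins data.frame with columns `id`, `sequence`.
#' @param path Output FASTA path.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                 proteins$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write an activity table
#'
#' @param proteins data.frame with columns `id`, `activity`.
#' @param path Output TSV path.
#' @export
write_activities <- function(proteins, path) {
  keep <- !is.na(proteins$activity)
  utils::write.table(
    data.frame(id = proteins$id[keep],
               activity = sprintf("%.12g", proteins$activity[keep])),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
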