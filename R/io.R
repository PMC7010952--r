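#' Read protein records from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are cleaned (uppercased, non-standard residues removed with a
#' warning).
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id`, `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- vapply(as.character(set), clean_sequence, character(1),
                 USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs)
}

#' Write protein records to a FASTA file
#'
#' @param proteins Data frame with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an interaction pair list
#'
#' Tab-separated file with at least three columns: `id_a`, `id_b`, `label`
#' (1 interacting / 0 non-interacting). Lines starting with `#` are skipped.
#'
#' @param path TSV path.
#' @return Data frame with columns `id_a`, `id_b`, `label` (integer).
#' @export
read_pairs <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no pair records in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad_len <- vapply(fields, length, integer(1)) < 3L
  if (any(bad_len)) {
    stop(sprintf("line %d: expected at least 3 tab-separated columns",
                 lineno[which(bad_len)[1]]))
  }
  lab_chr <- vapply(fields, `[[`, character(1), 3L)
  bad_lab <- !lab_chr %in% c("0", "1")
  if (any(bad_lab)) {
    stop(sprintf("line %d: label must be 0 or 1, got '%s'",
                 lineno[which(bad_lab)[1]], lab_chr[which(bad_lab)[1]]))
  }
  data.frame(id_a = vapply(fields, `[[`, character(1), 1L),
             id_b = vapply(fields, `[[`, character(1), 2L),
             label = as.integer(lab_chr))
}

#' Write an interaction pair list as TSV
#'
#' @param pairs Data frame with columns `id_a`, `id_b`, `label`.
#' @param path Output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("id_a", "id_b", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
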