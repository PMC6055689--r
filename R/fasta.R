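# FASTA input/output, backed by Biostrings. Library headers follow
# "<display_id>|<anchor>|<modified residue>".

#' Read amino-acid FASTA records
#'
#' Sequences are normalized to uppercase; lowercase input triggers a
#' warning. Identifiers are the full header lines (without `>`).
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id` and `sequence` (zero rows for an
#'   empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues normalized to uppercase in ", path)
    seqs <- toupper(seqs)
  }
  data.frame(id = names(set), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write amino-acid FASTA records
#'
#' Output is byte-stable given identical input (fixed width, no wrapping).
#'
#' @param records data.frame with columns `id` and `sequence`, or a
#'   [candidate_library] / list of libraries (headers then follow
#'   `"<display_id>|<anchor>|<modified residue>"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "candidate_library") ||
      (is.list(records) && !is.data.frame(records) &&
       all(vapply(records, inherits, TRUE, "candidate_library")))) {
    tab <- candidate_table(records)
    records <- data.frame(
      id = paste(tab$id, tab$anchor, tab$modified, sep = "|"),
      sequence = tab$sequence, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 20000L)
  invisible(path)
}
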