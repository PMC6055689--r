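# RNA secondary-structure module: reverse translation of candidate
# peptides to a coding transcript and a binary hairpin/no-hairpin call.
#
# The fold is a Nussinov-style base-pair maximization (nested structures,
# Watson-Crick + optional G.U wobble, minimum hairpin loop), followed by
# an explicit stem/loop classification rule. This is a deliberately simple,
# fully documented structure model: the downstream scoring scheme consumes
# only the binary hairpin outcome.

#' Reverse-translate a peptide to a coding RNA
#'
#' @param p A [peptide] or amino-acid string.
#' @param table A [codon_table()]; one codon per amino acid.
#' @param context5,context3 Optional flanking RNA context (e.g. vector
#'   sequence around the insert).
#' @return RNA string `context5 + codons + context3`.
#' @examples
#' reverse_translate("M")  # "AUG"
#' @export
reverse_translate <- function(p, table = codon_table(),
                              context5 = "", context3 = "") {
  sequence <- if (inherits(p, "peptide")) p$sequence else p
  chars <- .check_aa(sequence)
  if (length(chars) == 0L) stop("peptide must be non-empty", call. = FALSE)
  .check_rna(paste0(context5, context3), allow_empty = TRUE)
  codons <- as.character(table[chars])
  if (anyNA(codons))
    stop("table error: amino acid absent from codon table", call. = FALSE)
  paste0(context5, paste(codons, collapse = ""), context3)
}

.check_rna <- function(rna, allow_empty = FALSE) {
  if (nchar(rna) == 0L) {
    if (allow_empty) return(invisible(character()))
    stop("alphabet error: empty RNA", call. = FALSE)
  }
  chars <- strsplit(rna, "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "U"))
  if (length(bad))
    stop("alphabet error: invalid nucleotide(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(chars)
}

#' Fold an RNA by base-pair maximization
#'
#' Computes a nested secondary structure maximizing the number of base
#' pairs (Watson-Crick plus, optionally, G.U wobble) subject to a minimum
#' hairpin-loop size, by dynamic programming with a fixed, deterministic
#' traceback order.
#'
#' @param rna RNA string over `A`, `C`, `G`, `U`.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3, the standard steric minimum).
#' @param allow_wobble Allow G.U pairs (default TRUE).
#' @return Object of class `fold_result`: list with `rna`, `structure`
#'   (dot-bracket), `pair_count`, `pairing` (1-based partner vector, 0 =
#'   unpaired), and `stems`, a data.frame of maximal stacked-pair runs
#'   with columns `i`, `j` (outermost pair), `length`, `terminal`
#'   (whether the innermost pair encloses only unpaired bases) and
#'   `loop_length` (NA for non-terminal stems).
#' @examples
#' fold_max_pairs("GGGGAAAACCCC")
#' @export
fold_max_pairs <- function(rna, min_loop = 3L, allow_wobble = TRUE) {
  .check_rna(rna)
  pairing <- .nussinov_pairs(rna, as.integer(min_loop), isTRUE(allow_wobble))
  n <- nchar(rna)
  struct <- rep(".", n)
  struct[pairing > seq_len(n)] <- "("
  struct[pairing != 0L & pairing < seq_len(n)] <- ")"
  structure(
    list(rna = rna,
         structure = paste(struct, collapse = ""),
         pair_count = sum(pairing != 0L) %/% 2L,
         pairing = as.integer(pairing),
         stems = .find_stems(pairing)),
    class = "fold_result")
}

# maximal runs of stacked pairs (i,j),(i+1,j-1),... and their loop status
.find_stems <- function(pairing) {
  n <- length(pairing)
  opens <- which(pairing > seq_len(n))
  stems <- list()
  used <- logical(n)
  for (i in opens) {
    if (used[i]) next
    j <- pairing[i]
    len <- 1L
    while (i + len <= n && pairing[i + len] == j - len && j - len > i + len) {
      used[i + len] <- TRUE
      len <- len + 1L
    }
    inner_i <- i + len - 1L
    inner_j <- pairing[inner_i]
    enclosed <- if (inner_j - inner_i > 1L)
      pairing[(inner_i + 1L):(inner_j - 1L)] else integer()
    terminal <- all(enclosed == 0L)
    stems[[length(stems) + 1L]] <- data.frame(
      i = i, j = j, length = len, terminal = terminal,
      loop_length = if (terminal) inner_j - inner_i - 1L else NA_integer_)
  }
  if (!length(stems))
    return(data.frame(i = integer(), j = integer(), length = integer(),
                      terminal = logical(), loop_length = integer()))
  do.call(rbind, stems)
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result>", x$pair_count, "pair(s)\n")
  cat(x$rna, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Classify a fold as hairpin-forming
#'
#' TRUE iff some stem of at least `min_stem` consecutive stacked pairs
#' encloses a terminal loop whose length lies in `[loop_min, loop_max]` —
#' the stem-loop motif counted as an unfavorable transcript feature by the
#' scoring scheme.
#'
#' @param fold A [fold_max_pairs()] result.
#' @param min_stem Minimum stacked-pair run length (default 4).
#' @param loop_min,loop_max Terminal loop length bounds (defaults 3 and 8).
#' @return Logical.
#' @export
classify_hairpin <- function(fold, min_stem = 4L, loop_min = 3L,
                             loop_max = 8L) {
  stopifnot(inherits(fold, "fold_result"))
  st <- fold$stems
  if (!nrow(st)) return(FALSE)
  any(st$terminal & st$length >= min_stem &
        st$loop_length >= loop_min & st$loop_length <= loop_max)
}

#' Hairpin call for a candidate peptide's coding transcript
#'
#' Convenience wrapper: reverse-translate, fold, classify.
#'
#' @inheritParams reverse_translate
#' @inheritParams classify_hairpin
#' @param min_loop Passed to [fold_max_pairs()].
#' @return Logical hairpin flag.
#' @export
transcript_hairpin <- function(p, table = codon_table(),
                               context5 = "", context3 = "",
                               min_loop = 3L, min_stem = 4L,
                               loop_min = 3L, loop_max = 8L) {
  rna <- reverse_translate(p, table, context5, context3)
  classify_hairpin(fold_max_pairs(rna, min_loop = min_loop),
                   min_stem = min_stem, loop_min = loop_min,
                   loop_max = loop_max)
}
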