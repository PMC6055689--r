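# Candidate generation: epitope region extraction, anchor mutations, and
# saturation single-substitution libraries.
#
# All positions are 1-based protein codon numbers, as in the field notation
# "G12V" or "V7D"; internal string offsets are derived from the peptide's
# region_start.

#' The wild-type K-ras epitope region
#'
#' The exon-2 region of human K-ras spanning codons 4-18
#' (`YKLVVVGAGGVGKSA`), the sequence-manipulation window for mimotope
#' design. Codons 12 and 13 are the oncogenic anchor positions.
#'
#' @return A [peptide] spanning codons 4-18.
#' @export
kras_region <- function() {
  peptide("YKLVVVGAGGVGKSA", region_start = 4L, display_id = "wtKRAS")
}

#' Construct a peptide
#'
#' @param sequence Uppercase amino-acid string over the 20-letter alphabet.
#' @param region_start Protein coordinate (1-based codon number) of the
#'   first residue.
#' @param display_id Identifier string.
#' @param anchor,flank Optional [mutation_spec] annotations: the codon 12/13
#'   anchor mutation and the engineered flanking substitution.
#' @return Object of class `peptide`.
#' @export
peptide <- function(sequence, region_start = 4L, display_id = NA_character_,
                    anchor = NULL, flank = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  .check_aa(sequence)
  structure(
    list(sequence = sequence,
         region_start = as.integer(region_start),
         display_id = display_id,
         anchor = anchor,
         flank = flank),
    class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  span <- sprintf("codons %d-%d", x$region_start,
                  x$region_start + nchar(x$sequence) - 1L)
  ann <- c(if (!is.null(x$anchor)) format(x$anchor),
           if (!is.null(x$flank)) format(x$flank))
  cat(sprintf("<peptide %s> %s (%s)%s\n",
              if (is.na(x$display_id)) "" else x$display_id,
              x$sequence, span,
              if (length(ann)) paste0(" [", paste(ann, collapse = " + "), "]") else ""))
  invisible(x)
}

#' Parse or construct a point-mutation specification
#'
#' A mutation spec names a single substitution in protein coordinates,
#' e.g. `"G12V"` (glycine 12 to valine) or `mutation_spec(7, "V", "D")`.
#'
#' @param codon Either a notation string like `"G12V"`, or an integer codon
#'   number when `from` and `to` are given.
#' @param from,to One-letter residue codes (original and substituted).
#' @return Object of class `mutation_spec` with fields `codon`, `from`, `to`.
#' @examples
#' mutation_spec("G13D")
#' format(mutation_spec(7, "V", "D"))  # "V7D"
#' @export
mutation_spec <- function(codon, from = NULL, to = NULL) {
  if (is.character(codon) && is.null(from)) {
    m <- regmatches(codon, regexec("^([A-Z])([0-9]+)([A-Z])$", codon))[[1]]
    if (length(m) != 4L)
      stop(sprintf("cannot parse mutation notation '%s'", codon), call. = FALSE)
    from <- m[2]; to <- m[4]; codon <- as.integer(m[3])
  }
  stopifnot(from %in% aa_alphabet(), to %in% aa_alphabet(), codon >= 1L)
  structure(list(codon = as.integer(codon), from = from, to = to),
            class = "mutation_spec")
}

#' @export
format.mutation_spec <- function(x, ...) sprintf("%s%d%s", x$from, x$codon, x$to)

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation>", format(x), "\n")
  invisible(x)
}

#' Extract an epitope region from a full protein sequence
#'
#' @param full_protein Amino-acid string (e.g. a full-length 189-residue
#'   K-ras protein).
#' @param start_codon,end_codon 1-based inclusive protein coordinates.
#' @param display_id Identifier for the resulting peptide.
#' @return A [peptide] whose `region_start` records `start_codon`.
#' @examples
#' kras <- read_fasta(system.file("extdata", "kras_protein.fasta",
#'                                package = "mimorank"))
#' extract_region(kras$sequence[1], 4, 18)  # YKLVVVGAGGVGKSA
#' @export
extract_region <- function(full_protein, start_codon, end_codon,
                           display_id = NA_character_) {
  .check_aa(full_protein, "full_protein")
  n <- nchar(full_protein)
  if (!(start_codon >= 1L && start_codon <= end_codon && end_codon <= n))
    stop(sprintf(
      "coordinate error: region [%d, %d] out of bounds for a %d-residue protein",
      start_codon, end_codon, n), call. = FALSE)
  peptide(substr(full_protein, start_codon, end_codon),
          region_start = as.integer(start_codon), display_id = display_id)
}

#' Apply a point mutation to a peptide
#'
#' The spec's `from` residue must match the current residue at the codon;
#' a mismatch raises a consistency error, which guards against
#' coordinate-convention bugs. Codon 12/13 substitutions are recorded as
#' the anchor mutation, any other codon as the flanking substitution.
#'
#' @param p A [peptide].
#' @param spec A [mutation_spec] (or notation string).
#' @return The mutated [peptide] with its annotation updated.
#' @examples
#' apply_mutation(kras_region(), "G12V")
#' @export
apply_mutation <- function(p, spec) {
  stopifnot(inherits(p, "peptide"))
  if (is.character(spec)) spec <- mutation_spec(spec)
  idx <- spec$codon - p$region_start + 1L
  if (idx < 1L || idx > nchar(p$sequence))
    stop(sprintf("coordinate error: codon %d outside region codons %d-%d",
                 spec$codon, p$region_start,
                 p$region_start + nchar(p$sequence) - 1L), call. = FALSE)
  cur <- substr(p$sequence, idx, idx)
  if (cur != spec$from)
    stop(sprintf(
      "consistency error: %s expects '%s' at codon %d but peptide has '%s'",
      format(spec), spec$from, spec$codon, cur), call. = FALSE)
  seq2 <- p$sequence
  substr(seq2, idx, idx) <- spec$to
  out <- p
  out$sequence <- seq2
  out$display_id <- NA_character_  # the source id no longer applies
  if (spec$codon %in% c(12L, 13L)) out$anchor <- spec else out$flank <- spec
  out
}

#' Default flank codon set
#'
#' The 12 flanking positions at which single substitutions are enumerated
#' in paper-compatible mode: codons 4-11 and 15-18 (anchor codons 12/13 and
#' codon 14 excluded).
#'
#' @return Integer vector of codon numbers.
#' @export
default_flank_codons <- function() c(4:11, 15:18)

#' Enumerate a single-substitution mimotope library
#'
#' Starting from an anchor-mutated base peptide, emit one candidate per
#' (flank codon, amino acid) pair. In `paper_compat` mode the full
#' 20-letter alphabet is used at each position, retaining the no-op
#' substitution to the wild-type residue as a distinct catalog entry
#' (12 codons x 20 = 240 candidates with defaults); `strict_19` omits the
#' residue already present at each position (12 x 19 = 228). Order is
#' deterministic: codons ascending, residues in [aa_alphabet()] order.
#'
#' @param base A [peptide] carrying an anchor mutation (see
#'   [apply_mutation()]).
#' @param flank_codons Integer codon set; must exclude 12 and 13.
#' @param mode `"paper_compat"` or `"strict_19"`.
#' @return Object of class `candidate_library`: list with `anchor`,
#'   `mode`, `flank_codons`, `base`, and `candidates`, a data.frame with
#'   columns `id`, `sequence`, `anchor`, `flank_codon`, `flank_from`,
#'   `flank_to`, `modified` (notation such as `"V7D"`).
#' @examples
#' lib <- enumerate_library(apply_mutation(kras_region(), "G12A"))
#' nrow(lib$candidates)  # 240
#' @export
enumerate_library <- function(base,
                              flank_codons = default_flank_codons(),
                              mode = c("paper_compat", "strict_19")) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "peptide"))
  if (is.null(base$anchor))
    stop("configuration error: base peptide carries no anchor mutation",
         call. = FALSE)
  flank_codons <- sort(unique(as.integer(flank_codons)))
  if (any(flank_codons %in% c(12L, 13L)))
    stop("configuration error: flank codon set must exclude anchor codons 12 and 13",
         call. = FALSE)
  span <- base$region_start + c(0L, nchar(base$sequence) - 1L)
  if (any(flank_codons < span[1] | flank_codons > span[2]))
    stop("configuration error: flank codon outside the peptide region",
         call. = FALSE)

  aas <- aa_alphabet()
  rows <- list()
  for (codon in flank_codons) {
    idx <- codon - base$region_start + 1L
    cur <- substr(base$sequence, idx, idx)
    subs <- if (mode == "strict_19") setdiff(aas, cur) else aas
    for (aa in subs) {
      seq2 <- base$sequence
      substr(seq2, idx, idx) <- aa
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seq2, flank_codon = codon, flank_from = cur,
        flank_to = aa, stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, rows)
  cand$anchor <- format(base$anchor)
  cand$modified <- sprintf("%s%d%s", cand$flank_from, cand$flank_codon,
                           cand$flank_to)
  cand$id <- sprintf("%d-%s", seq_len(nrow(cand)), base$anchor$to)
  cand <- cand[, c("id", "sequence", "anchor", "flank_codon",
                   "flank_from", "flank_to", "modified")]
  structure(list(anchor = base$anchor, mode = mode,
                 flank_codons = flank_codons, base = base,
                 candidates = cand),
            class = "candidate_library")
}

#' @export
print.candidate_library <- function(x, ...) {
  cat(sprintf("<candidate_library> anchor %s, %d candidates (%s mode, %d flank codons)\n",
              format(x$anchor), nrow(x$candidates), x$mode,
              length(x$flank_codons)))
  print(utils::head(x$candidates, 5))
  if (nrow(x$candidates) > 5) cat("...\n")
  invisible(x)
}

#' Display identifier of a candidate within its library
#'
#' IDs follow the convention `"<n>-<X>"`: `n` is the 1-based enumeration
#' index in the library's deterministic order and `X` the anchor
#' mutation's substituted residue (so every G13D-library candidate ends in
#' `"-D"`). The enumeration order here is the package's own; published
#' identifiers from other orderings can be carried as aliases.
#'
#' @param library A [candidate_library].
#' @param index 1-based candidate index.
#' @return Identifier string.
#' @export
assign_display_id <- function(library, index) {
  stopifnot(inherits(library, "candidate_library"),
            index >= 1L, index <= nrow(library$candidates))
  sprintf("%d-%s", as.integer(index), library$anchor$to)
}

#' Enumerate libraries for several anchor mutations
#'
#' @param anchors Character vector of anchor notations (default the seven
#'   oncogenic variants `G12A/C/D/R/S/V` and `G13D`) or list of
#'   [mutation_spec].
#' @param wildtype A [peptide]; default [kras_region()].
#' @inheritParams enumerate_library
#' @return Named list of [candidate_library] (one per anchor). With
#'   defaults, 7 x 240 = 1,680 candidates in total.
#' @export
enumerate_all <- function(anchors = c("G12A", "G12C", "G12D", "G12R",
                                      "G12S", "G12V", "G13D"),
                          wildtype = kras_region(),
                          flank_codons = default_flank_codons(),
                          mode = c("paper_compat", "strict_19")) {
  mode <- match.arg(mode)
  if (length(anchors) == 0L)
    stop("configuration error: at least one anchor mutation is required",
         call. = FALSE)
  specs <- lapply(anchors, function(a)
    if (inherits(a, "mutation_spec")) a else mutation_spec(a))
  labels <- vapply(specs, format, "")
  if (anyDuplicated(labels))
    stop("configuration error: duplicate anchor mutation specs", call. = FALSE)
  libs <- lapply(specs, function(spec)
    enumerate_library(apply_mutation(wildtype, spec), flank_codons, mode))
  names(libs) <- labels
  libs
}

#' Bind all libraries into one candidate table
#'
#' Display identifiers are unique within a library but can repeat across
#' libraries sharing a substituted residue (G12D and G13D both suffix
#' `-D`), so a `uid` column (`"<anchor>:<id>"`) provides a global key.
#'
#' @param libs List of [candidate_library] as returned by [enumerate_all()].
#' @return data.frame of all candidates (columns as in
#'   [enumerate_library()] plus `uid`).
#' @export
candidate_table <- function(libs) {
  if (inherits(libs, "candidate_library")) libs <- list(libs)
  out <- do.call(rbind, lapply(libs, `[[`, "candidates"))
  rownames(out) <- NULL
  out$uid <- paste0(out$anchor, ":", out$id)
  out
}
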