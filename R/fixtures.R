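# Seedable synthetic fixtures: MHC prediction tables with controllable
# bin occupancy, and random peptide sets. Every fixture is regenerable
# from (seed, spec) alone.

#' Synthesize an MHC prediction table with controlled bin occupancy
#'
#' Generates a generic-dialect delimited prediction file whose
#' per-candidate best (minimum) scores fall into the conversion-scheme
#' bins according to `bin_occupancy`. Each candidate gets one record per
#' allele; the designated best record is drawn uniformly inside the target
#' bin and the remaining records are drawn at-or-above it. Identical seed
#' and spec give identical file bytes.
#'
#' @param candidate_ids Character vector of candidate identifiers.
#' @param path Output path (tab-delimited).
#' @param species `"human"` or `"mouse"`.
#' @param mhc_class `"I"` or `"II"`.
#' @param bin_occupancy Named probabilities over `c(high, intermediate,
#'   low)`; must sum to 1.
#' @param seed Integer seed.
#' @param table A [conversion_table()] supplying the bin edges.
#' @return `path`, invisibly; the drawn per-candidate best scores as
#'   attribute `best_scores`.
#' @export
synth_mhc_table <- function(candidate_ids, path,
                            species = c("human", "mouse"),
                            mhc_class = c("I", "II"),
                            bin_occupancy = c(high = 1, intermediate = 0,
                                              low = 0),
                            seed = 1L,
                            table = conversion_table()) {
  species <- match.arg(species)
  mhc_class <- match.arg(mhc_class)
  p <- bin_occupancy[c("high", "intermediate", "low")]
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("configuration error: bin_occupancy must be a distribution over high/intermediate/low",
         call. = FALSE)
  entry <- table[[if (mhc_class == "I") "mhc1" else "mhc2"]]
  # bin ranges on the raw (lower-is-better) scale
  lo <- c(max(entry$floor, 1e-3), entry$edges)
  hi <- c(entry$edges, entry$edges[2] * 2)
  alleles <- if (species == "mouse") {
    if (mhc_class == "I") c("H-2-Dd", "H-2-Kd", "H-2-Ld") else c("I-Ad", "I-Ed")
  } else {
    if (mhc_class == "I") c("HLA-A*02:01", "HLA-B*07:02") else
      c("HLA-DRB1*01:01", "HLA-DQB1*03:01")
  }
  units <- if (mhc_class == "I") "ic50_nM" else "percentile"
  sub_len <- if (mhc_class == "I") 9L else 15L

  set.seed(as.integer(seed))
  bins <- sample.int(3L, length(candidate_ids), replace = TRUE, prob = p)
  rows <- vector("list", length(candidate_ids))
  for (i in seq_along(candidate_ids)) {
    b <- bins[i]
    best <- runif(1, lo[b], hi[b])
    others <- runif(length(alleles) - 1L, best, hi[3])
    scores <- c(best, others)
    rows[[i]] <- data.frame(
      candidate_id = candidate_ids[i], allele = alleles,
      mhc_class = mhc_class, species = species,
      subpeptide = paste(sample(aa_alphabet(), sub_len, replace = TRUE),
                         collapse = ""),
      score = signif(scores, 8), score_units = units,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  best_scores <- setNames(vapply(split(tab$score, tab$candidate_id), min,
                                 numeric(1))[candidate_ids], candidate_ids)
  invisible(structure(path, best_scores = best_scores))
}

#' Generate random peptide FASTA records
#'
#' Uniform sequences over the 20-letter alphabet; seeded and reproducible.
#'
#' @param seed Integer seed.
#' @param n Number of peptides (>= 0).
#' @param length Peptide length (>= 7).
#' @return data.frame with columns `id`, `sequence`.
#' @export
random_peptides <- function(seed, n, length = 15L) {
  stopifnot(n >= 0L, length >= 7L)
  set.seed(as.integer(seed))
  if (n == 0L)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    id = sprintf("rp%0*d", nchar(as.character(n)), seq_len(n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(aa_alphabet(), length, replace = TRUE), collapse = ""),
      ""),
    stringsAsFactors = FALSE)
}
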