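# Ingestion of externally computed MHC class I/II binding predictions
# (IEDB-export-style delimited tables), allele filtering, and reduction to
# the single per-candidate raw score consumed by the conversion scheme.
# Trained MHC predictors are never re-implemented here; the toy
# position-weight-matrix predictor exists solely so the pipeline runs
# offline and is flagged synthetic in its output.

.mhc_dialects <- list(
  # column-name mapping per dialect: target field -> source column
  generic = c(candidate_id = "candidate_id", allele = "allele",
              mhc_class = "mhc_class", species = "species",
              subpeptide = "subpeptide", score = "score",
              score_units = "score_units"),
  iedb_mhci = c(candidate_id = "seq_num", allele = "allele",
                subpeptide = "peptide", score = "ic50"),
  iedb_mhcii = c(candidate_id = "seq_num", allele = "allele",
                 subpeptide = "peptide", score = "rank"))

#' Parse an MHC binding-prediction table
#'
#' Reads a delimited (tab or comma, sniffed from the header line) export
#' of per-allele, per-subpeptide binding predictions. Shipped dialects:
#' `"generic"` (all fields explicit), `"iedb_mhci"` (class I, IC50 nM),
#' `"iedb_mhcii"` (class II, percentile rank).
#'
#' @param path File path.
#' @param dialect Column-mapping dialect.
#' @param species,mhc_class Values filled in for dialects whose files do
#'   not carry them (`iedb_mhci` / `iedb_mhcii`).
#' @param lenient If TRUE, rows with non-numeric or non-positive scores are
#'   skipped with a collected warning; otherwise they are errors.
#' @return data.frame with columns `candidate_id`, `allele`, `mhc_class`
#'   (`"I"`/`"II"`), `species` (`"human"`/`"mouse"`), `subpeptide`,
#'   `score`, `score_units` (`"ic50_nM"`/`"percentile"`), `row` (source
#'   row number).
#' @export
parse_prediction_table <- function(path,
                                   dialect = c("generic", "iedb_mhci",
                                               "iedb_mhcii"),
                                   species = "human", mhc_class = NULL,
                                   lenient = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  map <- .mhc_dialects[[dialect]]
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  out <- data.frame(row = seq_len(nrow(raw)))
  for (field in names(map)) out[[field]] <- raw[[map[[field]]]]
  if (dialect == "iedb_mhci") {
    out$mhc_class <- "I"; out$score_units <- "ic50_nM"
  } else if (dialect == "iedb_mhcii") {
    out$mhc_class <- "II"; out$score_units <- "percentile"
  }
  if (!is.null(mhc_class)) out$mhc_class <- mhc_class
  if (!"species" %in% names(out) || all(is.na(out$species)))
    out$species <- species
  if (dialect != "generic") out$species <- species

  score_num <- suppressWarnings(as.numeric(out$score))
  bad <- which(is.na(score_num) | score_num <= 0)
  if (length(bad)) {
    msg <- sprintf("non-numeric or non-positive score in row(s) %s of %s",
                   paste(bad, collapse = ", "), path)
    if (!lenient) stop("parse error: ", msg, call. = FALSE)
    warning(msg, "; rows skipped")
    out <- out[-bad, , drop = FALSE]
    score_num <- score_num[-bad]
  }
  out$score <- score_num
  out[, c("candidate_id", "allele", "mhc_class", "species", "subpeptide",
          "score", "score_units", "row")]
}

#' Write predictions back to a generic-dialect table
#'
#' @param preds Prediction data.frame (see [parse_prediction_table()]).
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(preds, path) {
  cols <- c("candidate_id", "allele", "mhc_class", "species", "subpeptide",
            "score", "score_units")
  stopifnot(all(cols %in% names(preds)))
  write.table(preds[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Default allele filter
#'
#' Mouse defaults are the Balb/c *d*-haplotype allele sets: `H-2-Dd`,
#' `H-2-Kd`, `H-2-Ld` for class I and `I-Ad`, `I-Ed` for class II. For
#' human no allele restriction is applied by default (HLA-A/B/C class I;
#' HLA-DR/DP/DQ supertypes class II).
#'
#' @param species `"human"` or `"mouse"`.
#' @param mhc_class `"I"` or `"II"`.
#' @return List with `species`, `mhc_class`, `allowed_alleles` (NULL =
#'   unrestricted).
#' @export
allele_filter <- function(species = c("human", "mouse"),
                          mhc_class = c("I", "II")) {
  species <- match.arg(species)
  mhc_class <- match.arg(mhc_class)
  allowed <- if (species == "mouse") {
    if (mhc_class == "I") c("H-2-Dd", "H-2-Kd", "H-2-Ld")
    else c("I-Ad", "I-Ed")
  } else NULL
  list(species = species, mhc_class = mhc_class, allowed_alleles = allowed)
}

#' Filter predictions by species, class, and allele set
#'
#' Keeps exactly the records matching the filter, preserving order;
#' idempotent.
#'
#' @param preds Prediction data.frame.
#' @param filter An [allele_filter()] (or compatible list). Override the
#'   `allowed_alleles` element to restrict to an explicit set; an empty
#'   character vector keeps nothing.
#' @return Filtered data.frame.
#' @export
filter_alleles <- function(preds, filter) {
  keep <- preds$species == filter$species &
    preds$mhc_class == filter$mhc_class
  if (!is.null(filter$allowed_alleles))
    keep <- keep & preds$allele %in% filter$allowed_alleles
  preds[keep, , drop = FALSE]
}

#' Collapse predictions to one raw score per candidate
#'
#' Reduces across alleles and subpeptides; the default `"min"` takes the
#' strongest predicted binder (lower score = stronger binding for both
#' IC50 and percentile conventions), `"median"` the median score.
#'
#' @param preds Prediction data.frame (homogeneous `score_units`).
#' @param candidate_id Single candidate to aggregate; NULL aggregates all,
#'   returning a named vector.
#' @param method `"min"` or `"median"`.
#' @return Numeric score (or named vector over candidates).
#' @export
aggregate_best <- function(preds, candidate_id = NULL,
                           method = c("min", "median")) {
  method <- match.arg(method)
  if (!is.null(candidate_id))
    preds <- preds[preds$candidate_id %in% candidate_id, , drop = FALSE]
  if (!nrow(preds))
    stop("missing-data error: no prediction records for candidate",
         call. = FALSE)
  if (length(unique(preds$score_units)) > 1L)
    stop("unit error: mixed score units in aggregation", call. = FALSE)
  agg <- tapply(preds$score, preds$candidate_id,
                if (method == "min") min else median)
  out <- setNames(as.numeric(agg), names(agg))
  if (!is.null(candidate_id) && length(candidate_id) == 1L)
    unname(out[candidate_id]) else out
}

#' Toy position-weight-matrix MHC predictor (synthetic)
#'
#' A deterministic stand-in predictor so the pipeline is testable offline:
#' each k-mer of the peptide scores `exp(sum of position weights)`,
#' labeled as IC50 nM. It is NOT a biological predictor; outputs carry
#' allele `"toy"` prefixes and real studies must import externally
#' computed prediction tables instead.
#'
#' @param p A [peptide] or amino-acid string.
#' @param matrix Numeric matrix, `k` rows x 20 columns named by
#'   [aa_alphabet()].
#' @param k Subpeptide length; must equal `nrow(matrix)` and be <= the
#'   peptide length.
#' @param candidate_id Identifier used in the output records.
#' @param species,mhc_class Metadata for the records.
#' @return Prediction data.frame (one row per k-mer) with
#'   `allele = "toy-<species>-<class>"` and an attribute
#'   `synthetic = TRUE`.
#' @export
toy_matrix_predict <- function(p, matrix, k = nrow(matrix),
                               candidate_id = "candidate",
                               species = "human", mhc_class = "I") {
  sequence <- if (inherits(p, "peptide")) p$sequence else p
  chars <- .check_aa(sequence)
  if (!is.matrix(matrix) || nrow(matrix) != k || ncol(matrix) != 20L ||
      !all(aa_alphabet() %in% colnames(matrix)))
    stop("configuration error: matrix must be k x 20 with amino-acid columns",
         call. = FALSE)
  n <- length(chars)
  if (k > n)
    stop("configuration error: k exceeds peptide length", call. = FALSE)
  starts <- seq_len(n - k + 1L)
  scores <- vapply(starts, function(s) {
    exp(sum(matrix[cbind(seq_len(k), match(chars[s:(s + k - 1L)],
                                           colnames(matrix)))]))
  }, numeric(1))
  out <- data.frame(
    candidate_id = candidate_id,
    allele = sprintf("toy-%s-%s", species, mhc_class),
    mhc_class = mhc_class, species = species,
    subpeptide = vapply(starts, function(s)
      paste(chars[s:(s + k - 1L)], collapse = ""), ""),
    score = scores,
    score_units = if (mhc_class == "I") "ic50_nM" else "percentile",
    row = starts, stringsAsFactors = FALSE)
  attr(out, "synthetic") <- TRUE
  out
}
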