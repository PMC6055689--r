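# Sequence-propensity B-cell predictors: surface accessibility (Emini),
# hydrophilicity (Parker), antigenicity (Kolaskar-Tongaonkar), and a
# two-scale linear-epitope score (Parker + Levitt).
#
# A residue profile holds one value per window start; positions without a
# full window are undefined (absent), never zero-filled, so the max summary
# is not biased by edges.

.new_profile <- function(sequence, method, window, values) {
  structure(list(sequence = sequence, method = method,
                 window = as.integer(window), values = as.numeric(values)),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> %s, window %d, %d defined position(s)\n",
              x$method, x$window, length(x$values)))
  print(round(x$values, 4))
  invisible(x)
}

#' Sliding-window mean of a propensity scale
#'
#' `values[i]` is the arithmetic mean of the scale over the window starting
#' at residue `i`; there are `nchar(sequence) - window + 1` defined
#' positions.
#'
#' @param sequence Amino-acid string.
#' @param scale A [propensity_scale] (or named numeric vector over the
#'   20-letter alphabet).
#' @param window Window width (>= 1, <= sequence length).
#' @return A `residue_profile`.
#' @export
sliding_window_mean <- function(sequence, scale, window) {
  chars <- .check_aa(sequence)
  n <- length(chars)
  window <- as.integer(window)
  if (window < 1L) stop("window error: window must be >= 1", call. = FALSE)
  if (window > n)
    stop(sprintf("window error: window %d exceeds sequence length %d",
                 window, n), call. = FALSE)
  per_res <- as.numeric(scale[chars])
  if (anyNA(per_res))
    stop("alphabet error: residue missing from scale", call. = FALSE)
  cs <- cumsum(c(0, per_res))
  vals <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  .new_profile(sequence, attr(scale, "name") %||% "custom", window, vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.summarize_profile <- function(values, summary = c("max", "mean")) {
  summary <- match.arg(summary)
  if (summary == "max") max(values) else mean(values)
}

#' Emini surface accessibility
#'
#' Each window of `window` residues scores the product of the residues'
#' fractional surface probabilities divided by `norm^window`. With
#' `norm = "calibrated"` the constant is the arithmetic mean of the scale,
#' so the expected window score on uniformly random composition is exactly
#' 1.0; `norm = 0.37` applies the constant printed in the original
#' hexapeptide formulation (see the methods vignette for why the two
#' differ on this scale).
#'
#' @param sequence Amino-acid string of length >= `window`.
#' @param window Window width, default 6 (hexapeptide regions).
#' @param norm `"calibrated"` or a positive number.
#' @param summary Peptide-level reduction over windows: `"max"` (default,
#'   best surface-exposed region) or `"mean"`.
#' @return List with `profile` (a `residue_profile` of window scores) and
#'   `peptide_score`.
#' @export
emini_accessibility <- function(sequence, window = 6L, norm = "calibrated",
                                summary = c("max", "mean")) {
  scale <- propensity_scale("emini")
  chars <- .check_aa(sequence)
  n <- length(chars)
  window <- as.integer(window)
  if (n < window)
    stop(sprintf("window error: need >= %d residues", window), call. = FALSE)
  const <- if (identical(norm, "calibrated")) mean(scale) else as.numeric(norm)
  stopifnot(is.finite(const), const > 0)
  lw <- log(as.numeric(scale[chars]))
  cs <- cumsum(c(0, lw))
  vals <- exp(cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
              - window * log(const))
  prof <- .new_profile(sequence, "emini_sa", window, vals)
  list(profile = prof,
       peptide_score = .summarize_profile(vals, match.arg(summary)))
}

#' Parker hydrophilicity
#'
#' Window mean of the Parker scale; the peptide-level score is the most
#' hydrophilic window by default.
#'
#' @inheritParams emini_accessibility
#' @param window Window width, default 7.
#' @return List with `profile` and `peptide_score`.
#' @export
parker_hydrophilicity <- function(sequence, window = 7L,
                                  summary = c("max", "mean")) {
  prof <- sliding_window_mean(sequence, propensity_scale("parker"), window)
  list(profile = prof,
       peptide_score = .summarize_profile(prof$values, match.arg(summary)))
}

#' Kolaskar-Tongaonkar antigenicity
#'
#' Window mean of the antigenic-propensity scale; values of 1.0 and above
#' indicate antigenic windows.
#'
#' @inheritParams parker_hydrophilicity
#' @return List with `profile` and `peptide_score`.
#' @export
kolaskar_antigenicity <- function(sequence, window = 7L,
                                  summary = c("max", "mean")) {
  prof <- sliding_window_mean(sequence, propensity_scale("kolaskar"), window)
  list(profile = prof,
       peptide_score = .summarize_profile(prof$values, match.arg(summary)))
}

#' Two-scale linear-epitope score
#'
#' Per-position score is a weighted sum of Parker-hydrophilicity and
#' Levitt reverse-turn window means, a sequence-profile surrogate for
#' HMM-based linear-epitope predictors (externally computed per-residue
#' scores can be supplied downstream instead). Scores above 0.35 are
#' conventionally considered favorable.
#'
#' @inheritParams parker_hydrophilicity
#' @param parker_weight,levitt_weight Finite weights, default 0.5 each.
#' @return List with `profile` and `peptide_score`.
#' @export
linear_epitope_score <- function(sequence, parker_weight = 0.5,
                                 levitt_weight = 0.5, window = 7L,
                                 summary = c("max", "mean")) {
  stopifnot(is.finite(parker_weight), is.finite(levitt_weight))
  pk <- sliding_window_mean(sequence, propensity_scale("parker"), window)
  lv <- sliding_window_mean(sequence, propensity_scale("levitt"), window)
  vals <- parker_weight * pk$values + levitt_weight * lv$values
  prof <- .new_profile(sequence, "linear_epitope", as.integer(window), vals)
  list(profile = prof,
       peptide_score = .summarize_profile(vals, match.arg(summary)))
}

#' Compute the four B-cell raw scores for a candidate
#'
#' Bundles [emini_accessibility()] (SA), [parker_hydrophilicity()] (HY),
#' [kolaskar_antigenicity()] (AT) and [linear_epitope_score()] (LE) with
#' default settings. Deterministic: identical peptides give identical
#' scores.
#'
#' @param p A [peptide] or amino-acid string of length >= 7.
#' @param summary Window-to-peptide reduction, `"max"` or `"mean"`.
#' @return Named list `sa`, `hy`, `at`, `le` of finite raw scores.
#' @export
score_candidate_bcell <- function(p, summary = "max") {
  sequence <- if (inherits(p, "peptide")) p$sequence else p
  if (nchar(sequence) < 7L)
    stop("window error: peptide must have >= 7 residues", call. = FALSE)
  list(sa = emini_accessibility(sequence, summary = summary)$peptide_score,
       hy = parker_hydrophilicity(sequence, summary = summary)$peptide_score,
       at = kolaskar_antigenicity(sequence, summary = summary)$peptide_score,
       le = linear_epitope_score(sequence, summary = summary)$peptide_score)
}
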