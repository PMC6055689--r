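# End-to-end orchestration: generate -> predict -> fold -> convert -> rank.

#' Run the full mimotope design pipeline
#'
#' Enumerates candidate libraries, computes the four B-cell propensity
#' scores and the transcript hairpin flag for every candidate, obtains the
#' four MHC raw scores (imported prediction tables or the synthetic toy
#' predictor), converts all raw values through the conversion scheme, and
#' returns the ranked table. Deterministic given the configuration (the
#' only randomness is the toy-MHC weight draw, controlled by
#' `config$seed`).
#'
#' @param config List of configuration keys:
#' \describe{
#'   \item{wildtype}{Amino-acid string or FASTA path of the source protein
#'     (default: the shipped K-ras region).}
#'   \item{region}{`c(start, end)` protein coordinates, default `c(4, 18)`.}
#'   \item{anchors}{Anchor mutation notations, default the seven
#'     G12A/C/D/R/S/V + G13D variants.}
#'   \item{mode}{`"paper_compat"` (default) or `"strict_19"`.}
#'   \item{flank_codons}{Default [default_flank_codons()].}
#'   \item{mhc}{Either `list(mode = "toy", seed = <int>)` (default seed 1)
#'     or `list(mode = "import", human_mhc1 =, human_mhc2 =, mouse_mhc1 =,
#'     mouse_mhc2 = <paths>, dialects = ...)` with candidate ids matching
#'     the `uid` column.}
#'   \item{conversion}{A [conversion_table()].}
#'   \item{codon_table}{A [codon_table()].}
#'   \item{top_n}{Shortlist size; NULL ranks everything (default 20).}
#'   \item{seed}{Convenience alias for `mhc$seed`.}
#' }
#' @param quiet Suppress per-stage record-count messages.
#' @return A `ranked_table` of the shortlist, with the full ranked table in
#'   attribute `full` and the library list in attribute `libraries`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  region <- config$region %||% c(4L, 18L)
  wt <- config$wildtype %||% kras_region()
  if (is.character(wt)) {
    if (file.exists(wt)) wt <- read_fasta(wt)$sequence[1]
    wt <- extract_region(wt, region[1], region[2])
  }
  anchors <- config$anchors %||% c("G12A", "G12C", "G12D", "G12R",
                                   "G12S", "G12V", "G13D")
  mode <- config$mode %||% "paper_compat"
  flanks <- config$flank_codons %||% default_flank_codons()
  ctab <- config$conversion %||% conversion_table()
  cod <- config$codon_table %||% codon_table()

  libs <- enumerate_all(anchors, wildtype = wt, flank_codons = flanks,
                        mode = mode)
  cand <- candidate_table(libs)
  say("generate: %d candidates across %d libraries", nrow(cand), length(libs))

  bc <- vapply(cand$sequence, function(s)
    unlist(score_candidate_bcell(s)), numeric(4))
  cand$sa <- bc["sa", ]; cand$hy <- bc["hy", ]
  cand$at <- bc["at", ]; cand$le <- bc["le", ]
  say("predict-bcell: %d candidates scored", nrow(cand))

  cand$hairpin <- vapply(cand$sequence, function(s)
    transcript_hairpin(s, table = cod), logical(1))
  say("fold: %d hairpin-forming transcript(s)", sum(cand$hairpin))

  mhc_cfg <- config$mhc %||% list(mode = "toy")
  if (identical(mhc_cfg$mode, "toy")) {
    seed <- mhc_cfg$seed %||% config$seed %||% 1L
    mhc <- .toy_mhc_scores(cand, seed)
  } else if (identical(mhc_cfg$mode, "import")) {
    mhc <- .import_mhc_scores(cand, mhc_cfg)
  } else {
    stop("configuration error: mhc mode must be 'toy' or 'import'",
         call. = FALSE)
  }
  cand <- cbind(cand, mhc)
  say("mhc: 4 score streams attached")

  scored <- category_totals(convert_scores(cand, ctab))
  ranked <- rank_candidates(scored)
  say("rank: %d rows, key %s", nrow(ranked), attr(ranked, "ranking_key"))
  top_n <- config$top_n %||% 20L
  out <- if (is.null(top_n)) ranked else shortlist(ranked, top_n)
  attr(out, "full") <- ranked
  attr(out, "libraries") <- libs
  out
}

# synthetic MHC raw scores from seeded toy weight matrices (one per
# species x class); class I scaled to an nM-like range, class II to a
# percentile-like range
.toy_mhc_scores <- function(cand, seed) {
  set.seed(as.integer(seed))
  streams <- list(
    mhc1_human = list(k = 9L, base = log(150)),
    mhc2_human = list(k = 13L, base = log(6)),
    mhc1_mouse = list(k = 9L, base = log(150)),
    mhc2_mouse = list(k = 13L, base = log(6)))
  out <- list()
  for (nm in names(streams)) {
    st <- streams[[nm]]
    W <- matrix(stats::rnorm(st$k * 20L, sd = 0.35), nrow = st$k,
                dimnames = list(NULL, aa_alphabet()))
    cls <- if (grepl("mhc1", nm)) "I" else "II"
    sp <- sub(".*_", "", nm)
    out[[nm]] <- vapply(seq_len(nrow(cand)), function(i) {
      preds <- toy_matrix_predict(cand$sequence[i], W, st$k,
                                  candidate_id = cand$uid[i],
                                  species = sp, mhc_class = cls)
      exp(st$base) * aggregate_best(preds, cand$uid[i])
    }, numeric(1))
  }
  as.data.frame(out)
}

.import_mhc_scores <- function(cand, cfg) {
  need <- c("human_mhc1", "human_mhc2", "mouse_mhc1", "mouse_mhc2")
  if (!all(need %in% names(cfg)))
    stop("configuration error: import mode needs paths ",
         paste(need, collapse = ", "), call. = FALSE)
  dialects <- cfg$dialects %||%
    c(human_mhc1 = "generic", human_mhc2 = "generic",
      mouse_mhc1 = "generic", mouse_mhc2 = "generic")
  out <- list()
  for (nm in need) {
    sp <- sub("_.*", "", nm)
    cls <- if (grepl("mhc1", nm)) "I" else "II"
    preds <- parse_prediction_table(cfg[[nm]], dialect = dialects[[nm]],
                                    species = sp, mhc_class = cls)
    preds <- filter_alleles(preds, allele_filter(sp, cls))
    agg <- aggregate_best(preds)
    vals <- unname(agg[cand$uid])
    if (anyNA(vals))
      stop("missing-data error: no ", nm, " prediction for candidate(s) ",
           paste(utils::head(cand$uid[is.na(vals)], 3), collapse = ", "),
           call. = FALSE)
    out[[sub("^(human|mouse)_(mhc[12])$", "\\2_\\1", nm)]] <- vals
  }
  as.data.frame(out)
}
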