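# The priority-weighted scoring and ranking system: raw parameter values
# are converted to fixed percentage weights via a binned scheme, summed
# into T-cell (MHC II + MHC I, max 58 + 42 = 100) and B-cell
# (SA + HY + AT + LE + RNA2, max 34 + 29 + 19 + 12 + 6 = 100) category
# totals, and candidates are ranked with deterministic tie-breaking by
# parameter priority.

#' Default raw-score conversion scheme
#'
#' Bin boundaries and weight percentages per parameter. For lower-is-better
#' parameters (MHC, IC50/percentile conventions) and higher-is-better
#' parameters (SA/HY/AT/LE) bins are half-open intervals anchored at the
#' printed lower edges, so every real value maps to exactly one bin;
#' values below the lowest printed bin are clamped into the nearest bin
#' with a diagnostic. RNA2 is categorical on the hairpin flag.
#'
#' Defaults: MHC II 0.01-4.65 -> 58, 4.66-9.28 -> 39, >= 9.29 -> 20;
#' MHC I (nM) 0-50 -> 42, 51-500 -> 28, >= 501 -> 14 (unbounded above);
#' SA 2.531-3.149 -> 34, 1.913-2.530 -> 23, 1.294-1.912 -> 12;
#' HY 3.444-4.614 -> 29, 2.615-3.443 -> 19, 0-2.614 -> 9;
#' AT >= 1.0 -> 19, < 1.0 -> 13; LE >= 5.82 -> 12, 0.36-5.81 -> 8,
#' 0-0.35 -> 4; RNA2 no hairpin -> 6, hairpin -> 4.
#'
#' @return Object of class `conversion_table`: named list of parameter
#'   entries, each with `direction` (`"lower"`, `"higher"`,
#'   `"categorical"`), `edges` (interior lower edges, most favorable bin
#'   first) and `weights` (percent, most favorable first).
#' @export
conversion_table <- function() {
  structure(list(
    mhc2 = list(direction = "lower", edges = c(4.66, 9.29),
                weights = c(58, 39, 20), floor = 0.01),
    mhc1 = list(direction = "lower", edges = c(51, 501),
                weights = c(42, 28, 14), floor = 0),
    sa   = list(direction = "higher", edges = c(2.531, 1.913),
                weights = c(34, 23, 12), floor = 1.294),
    hy   = list(direction = "higher", edges = c(3.444, 2.615),
                weights = c(29, 19, 9), floor = 0),
    at   = list(direction = "higher", edges = 1.0,
                weights = c(19, 13), floor = -Inf),
    le   = list(direction = "higher", edges = c(5.82, 0.36),
                weights = c(12, 8, 4), floor = 0),
    rna2 = list(direction = "categorical", weights = c(no_hairpin = 6,
                                                       hairpin = 4))),
    class = "conversion_table")
}

#' @export
print.conversion_table <- function(x, ...) {
  cat("<conversion_table> weight (%) by bin, most favorable first\n")
  for (p in names(x)) {
    e <- x[[p]]
    cat(sprintf("  %-4s [%s] weights: %s%s\n", p, e$direction,
                paste(e$weights, collapse = "/"),
                if (!is.null(e$edges))
                  paste0("  edges: ", paste(e$edges, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Convert a raw parameter value to its weight percentage
#'
#' @param parameter One of `"mhc2"`, `"mhc1"`, `"sa"`, `"hy"`, `"at"`,
#'   `"le"`, `"rna2"`.
#' @param raw Finite numeric raw score, or logical hairpin flag for
#'   `"rna2"`.
#' @param table A [conversion_table()].
#' @param warn_clamp Emit a diagnostic when a value below the lowest
#'   printed bin is clamped in.
#' @return Weight percentage (numeric). Vectorized over `raw`.
#' @examples
#' convert_raw("mhc2", 2.0)    # 58
#' convert_raw("mhc1", 5500)   # 14
#' convert_raw("at", c(1.0, 0.999))  # 19 13
#' convert_raw("rna2", FALSE)  # 6
#' @export
convert_raw <- function(parameter, raw, table = conversion_table(),
                        warn_clamp = TRUE) {
  entry <- table[[match.arg(parameter, names(table))]]
  if (entry$direction == "categorical") {
    if (!is.logical(raw))
      stop("binning error: rna2 expects a logical hairpin flag",
           call. = FALSE)
    return(ifelse(raw, entry$weights[["hairpin"]],
                  entry$weights[["no_hairpin"]]))
  }
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)))
    stop("binning error: raw value must be finite", call. = FALSE)
  if (entry$direction == "lower") {
    if (warn_clamp && any(raw < entry$floor))
      warning(sprintf("raw value below lowest printed edge (%g); clamped into the most favorable bin",
                      entry$floor))
    idx <- findInterval(raw, entry$edges) + 1L   # < edge1 -> bin 1
  } else {
    if (warn_clamp && any(raw < entry$floor))
      warning(sprintf("raw value below lowest printed edge (%g); clamped into the least favorable bin",
                      entry$floor))
    idx <- vapply(raw, function(v) {
      hit <- which(v >= entry$edges)
      if (length(hit)) hit[1] else length(entry$weights)
    }, integer(1))
  }
  unname(entry$weights[idx])
}

#' Equal-width bin calibration
#'
#' Splits an observed raw-score range into `k` contiguous equal-width
#' intervals; an optional alternative to the fixed printed bins (the SA
#' boundaries are consistent with equal-width terciles of an observed
#' range).
#'
#' @param observed_min,observed_max Observed range, `min < max`.
#' @param k Number of bins (>= 2).
#' @return Numeric vector of `k + 1` boundaries.
#' @examples
#' calibrate_equal_width_bins(1.294, 3.149)  # cuts near 1.912 and 2.530
#' @export
calibrate_equal_width_bins <- function(observed_min, observed_max, k = 3L) {
  if (!(observed_min < observed_max))
    stop("calibration error: degenerate range", call. = FALSE)
  if (k < 2L) stop("calibration error: k must be >= 2", call. = FALSE)
  seq(observed_min, observed_max, length.out = k + 1L)
}

#' Convert a raw-score table to weight columns
#'
#' @param raw_scores data.frame with identifier columns plus raw columns
#'   among `mhc2_human`, `mhc1_human`, `mhc2_mouse`, `mhc1_mouse`, `sa`,
#'   `hy`, `at`, `le`, `hairpin` (logical).
#' @param table A [conversion_table()].
#' @param warn_clamp Passed to [convert_raw()].
#' @return The input with added `conv_*` weight columns.
#' @export
convert_scores <- function(raw_scores, table = conversion_table(),
                           warn_clamp = TRUE) {
  param_of <- c(mhc2_human = "mhc2", mhc1_human = "mhc1",
                mhc2_mouse = "mhc2", mhc1_mouse = "mhc1",
                sa = "sa", hy = "hy", at = "at", le = "le",
                hairpin = "rna2")
  out <- raw_scores
  for (col in names(param_of)) {
    if (!col %in% names(raw_scores)) next
    conv_col <- if (col == "hairpin") "conv_rna2" else paste0("conv_", col)
    out[[conv_col]] <- convert_raw(param_of[[col]], raw_scores[[col]],
                                   table, warn_clamp = warn_clamp)
  }
  out
}

.tcell_members <- function(species)
  paste0("conv_", c("mhc2", "mhc1"), "_", species)
.bcell_members <- c("conv_sa", "conv_hy", "conv_at", "conv_le", "conv_rna2")

#' Sum converted weights into category totals
#'
#' Adds `tcell_human` and/or `tcell_mouse` (`= MHC II + MHC I` per
#' species, max 100), `bcell` (`= SA + HY + AT + LE + RNA2`, max 100),
#' and `grand_total` (sum of the categories present). A category is
#' computed only when all of its member columns are present; a partially
#' present category is a completeness error.
#'
#' @param scorecards data.frame with `conv_*` columns (see
#'   [convert_scores()]).
#' @return The input with total columns added.
#' @export
category_totals <- function(scorecards) {
  out <- scorecards
  grand <- rep(0, nrow(out))
  any_cat <- FALSE
  for (sp in c("human", "mouse")) {
    members <- .tcell_members(sp)
    present <- members %in% names(out)
    if (all(present)) {
      out[[paste0("tcell_", sp)]] <- rowSums(out[, members, drop = FALSE])
      grand <- grand + out[[paste0("tcell_", sp)]]
      any_cat <- TRUE
    } else if (any(present)) {
      stop("completeness error: missing converted field(s): ",
           paste(members[!present], collapse = ", "), call. = FALSE)
    }
  }
  present <- .bcell_members %in% names(out)
  if (all(present)) {
    out$bcell <- rowSums(out[, .bcell_members, drop = FALSE])
    grand <- grand + out$bcell
    any_cat <- TRUE
  } else if (any(present)) {
    stop("completeness error: missing converted field(s): ",
         paste(.bcell_members[!present], collapse = ", "), call. = FALSE)
  }
  if (!any_cat)
    stop("completeness error: no complete category present", call. = FALSE)
  out$grand_total <- grand
  out
}

# tie-break column order: stated parameter priority (MHC class II >
# MHC class I > SA > HY > AT > LE > RNA 2), human before mouse, then id
.priority_columns <- function(df) {
  cand <- c("conv_mhc2_human", "conv_mhc2_mouse",
            "conv_mhc1_human", "conv_mhc1_mouse",
            "conv_sa", "conv_hy", "conv_at", "conv_le", "conv_rna2")
  cand[cand %in% names(df)]
}

#' Rank candidates in descending order of immunogenicity
#'
#' Sorts by the ranking key (descending), breaking ties by the individual
#' converted weights in the stated parameter priority order
#' (MHC class II > MHC class I > surface accessibility > hydrophilicity >
#' antigenicity > linear epitope > RNA secondary structure; human before
#' mouse), then by candidate identifier, so the order is a total,
#' permutation-invariant order.
#'
#' @param scorecards data.frame with total columns (see
#'   [category_totals()]).
#' @param key Ranking key column: `"grand_total"` (default, sum of all
#'   categories present) or a single category total.
#' @return Object of class `ranked_table`: the sorted data.frame with a
#'   `rank` column and attributes `ranking_key` and `tie_break`.
#' @export
rank_candidates <- function(scorecards,
                            key = c("grand_total", "tcell_human",
                                    "tcell_mouse", "bcell")) {
  key <- match.arg(key)
  if (!key %in% names(scorecards))
    stop("completeness error: ranking key '", key, "' not present",
         call. = FALSE)
  tie_cols <- .priority_columns(scorecards)
  id_col <- if ("uid" %in% names(scorecards)) "uid" else "id"
  keys <- c(list(-scorecards[[key]]),
            lapply(tie_cols, function(cn) -scorecards[[cn]]),
            list(scorecards[[id_col]]))
  ord <- do.call(order, keys)
  out <- scorecards[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("ranked_table", "data.frame"),
            ranking_key = key,
            tie_break = paste("descending converted weights in priority order",
                              "(MHC II > MHC I > SA > HY > AT > LE > RNA2,",
                              "human before mouse), then candidate id"))
}

#' Keep the top candidates of a ranked table
#'
#' @param ranked A [rank_candidates()] result.
#' @param n Number of rows to keep (default 20); the whole table if fewer.
#' @return The truncated `ranked_table`.
#' @export
shortlist <- function(ranked, n = 20L) {
  stopifnot(inherits(ranked, "ranked_table"), n >= 1L)
  out <- ranked[seq_len(min(n, nrow(ranked))), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(ranked),
            ranking_key = attr(ranked, "ranking_key"),
            tie_break = attr(ranked, "tie_break"))
}

.report_columns <- list(
  human_tcell = c("id", "sequence", "anchor", "modified",
                  "conv_mhc2_human", "conv_mhc1_human", "tcell_human"),
  mouse_tcell = c("id", "sequence", "anchor", "modified",
                  "conv_mhc2_mouse", "conv_mhc1_mouse", "tcell_mouse"),
  bcell = c("id", "sequence", "anchor", "modified", "conv_sa", "conv_hy",
            "conv_at", "conv_le", "conv_rna2", "bcell"),
  combined = NULL)

#' Write a ranked report
#'
#' Tab-delimited, byte-stable given identical input. Styles mirror the
#' published table layouts: `human_tcell` / `mouse_tcell` (id, sequence,
#' anchor, modified residue, MHC II, MHC I, total), `bcell` (id, sequence,
#' anchor, modified residue, SA, HY, AT, LE, RNA2, total), `combined`
#' (every column).
#'
#' @param ranked A `ranked_table` (or scorecard data.frame).
#' @param style Report layout.
#' @param path Output path.
#' @return `path`, invisibly. An empty table writes a header-only file
#'   with a warning.
#' @export
write_report <- function(ranked,
                         style = c("combined", "human_tcell",
                                   "mouse_tcell", "bcell"),
                         path) {
  style <- match.arg(style)
  cols <- .report_columns[[style]]
  df <- as.data.frame(ranked)
  if (!is.null(cols)) {
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("completeness error: missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if ("rank" %in% names(df)) cols <- c("rank", cols)
    df <- df[, cols, drop = FALSE]
  }
  if (!nrow(df)) warning("writing header-only report: empty table")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
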