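test_that("raw-to-weight conversion reproduces the published bin scheme", {
  expect_equal(convert_raw("mhc2", 2.0), 58)
  expect_equal(convert_raw("mhc2", 6.0), 39)
  expect_equal(convert_raw("mhc2", 9.29), 20)
  expect_equal(convert_raw("mhc1", 30), 42)
  expect_equal(convert_raw("mhc1", 200), 28)
  expect_equal(convert_raw("mhc1", 5500), 14)  # unbounded low bin
  expect_equal(convert_raw("at", c(1.0, 0.999)), c(19, 13))
  expect_equal(convert_raw("le", c(6.0, 3.0, 0.2)), c(12, 8, 4))
  expect_equal(convert_raw("rna2", c(FALSE, TRUE)), c(6, 4))
  # values below the lowest printed edge clamp with a diagnostic
  expect_warning(w <- convert_raw("sa", 0.5), "clamped")
  expect_equal(w, 12)
  expect_warning(w2 <- convert_raw("mhc2", 0.001), "clamped")
  expect_equal(w2, 58)
  expect_error(convert_raw("hy", Inf), "binning error")
  expect_error(convert_raw("rna2", 1.5), "binning error")
})

test_that("weights are monotone in raw-score favorability across every boundary", {
  tab <- conversion_table()
  eps <- 1e-9
  for (param in c("mhc2", "mhc1", "sa", "hy", "at", "le")) {
    entry <- tab[[param]]
    edges <- sort(entry$edges)
    grid <- sort(unique(c(edges - eps, edges, edges + eps,
                          seq(max(min(edges) / 2, entry$floor),
                              max(edges) * 2, length.out = 41))))
    grid <- grid[grid >= entry$floor]
    w <- suppressWarnings(convert_raw(param, grid, tab))
    if (entry$direction == "lower") {
      expect_true(all(diff(w) <= 0), info = param)  # lower raw = better
    } else {
      expect_true(all(diff(w) >= 0), info = param)  # higher raw = better
    }
    expect_setequal(unique(w), entry$weights)
  }
})

test_that("equal-width calibration recovers the printed accessibility terciles", {
  cuts <- calibrate_equal_width_bins(1.294, 3.149)
  expect_equal(cuts[2], 1.912, tolerance = 1e-3)
  expect_equal(cuts[3], 2.530, tolerance = 1e-3)
  expect_equal(calibrate_equal_width_bins(0, 3), c(0, 1, 2, 3))
  widths <- diff(calibrate_equal_width_bins(0.2, 7.7, 5))
  expect_equal(widths, rep(widths[1], 5))
  expect_error(calibrate_equal_width_bins(1, 1), "calibration error")
  expect_error(calibrate_equal_width_bins(0, 1, k = 1), "calibration error")
})

test_that("category totals sum converted weights with completeness checks", {
  df <- data.frame(id = "x", conv_mhc2_human = 58, conv_mhc1_human = 42,
                   conv_mhc2_mouse = 58, conv_mhc1_mouse = 28,
                   conv_sa = 34, conv_hy = 29, conv_at = 13, conv_le = 12,
                   conv_rna2 = 6)
  tot <- category_totals(df)
  expect_equal(tot$tcell_human, 100)
  expect_equal(tot$tcell_mouse, 86)
  expect_equal(tot$bcell, 94)
  expect_equal(tot$grand_total, 280)

  incomplete <- df; incomplete$conv_mhc1_mouse <- NULL
  expect_error(category_totals(incomplete), "conv_mhc1_mouse")
  expect_error(category_totals(data.frame(id = "x")), "completeness error")
})

test_that("category maxima of 100 are attained iff every member is top-bin", {
  tab <- conversion_table()
  top <- data.frame(conv_mhc2_human = 58, conv_mhc1_human = 42,
                    conv_sa = 34, conv_hy = 29, conv_at = 19,
                    conv_le = 12, conv_rna2 = 6)
  tot <- category_totals(top)
  expect_equal(tot$tcell_human, 100)
  expect_equal(tot$bcell, 100)
  # dropping any single member below its top bin breaks its category maximum
  drops <- list(conv_mhc2_human = 39, conv_mhc1_human = 28, conv_sa = 23,
                conv_hy = 19, conv_at = 13, conv_le = 8, conv_rna2 = 4)
  for (col in names(drops)) {
    d <- top; d[[col]] <- drops[[col]]
    tot_d <- category_totals(d)
    if (col %in% c("conv_mhc2_human", "conv_mhc1_human")) {
      expect_lt(tot_d$tcell_human, 100)
      expect_equal(tot_d$bcell, 100)
    } else {
      expect_lt(tot_d$bcell, 100)
      expect_equal(tot_d$tcell_human, 100)
    }
  }
})

test_that("published golden scorecards reproduce exactly under conversion and totals", {
  g <- golden_scorecards()
  expect_equal(nrow(g), 23L)
  # raw values drawn inside the implied bins convert back to the printed
  # weights and totals, with no tolerance
  raw <- data.frame(
    id = g$id,
    mhc2_human = raw_for_weight("mhc2", g$conv_mhc2_human),
    mhc1_human = raw_for_weight("mhc1", g$conv_mhc1_human),
    mhc2_mouse = raw_for_weight("mhc2", g$conv_mhc2_mouse),
    mhc1_mouse = raw_for_weight("mhc1", g$conv_mhc1_mouse),
    sa = raw_for_weight("sa", g$conv_sa),
    hy = raw_for_weight("hy", g$conv_hy),
    at = raw_for_weight("at", g$conv_at),
    le = raw_for_weight("le", g$conv_le),
    hairpin = g$conv_rna2 == 4)
  out <- category_totals(convert_scores(raw))
  for (col in c("conv_mhc2_human", "conv_mhc1_human", "conv_mhc2_mouse",
                "conv_mhc1_mouse", "conv_sa", "conv_hy", "conv_at",
                "conv_le", "conv_rna2", "tcell_human", "tcell_mouse",
                "bcell")) {
    expect_identical(as.numeric(out[[col]]), as.numeric(g[[col]]),
                     label = col)
  }
  # the only inter-table sequence conflict is candidate 78-D, kept flagged
  expect_equal(g$id[g$sequence_discrepancy], "78-D")
})

test_that("ranking is a permutation-invariant total order with priority tie-breaks", {
  # a and b have equal grand totals (128) but MHC II weights 58 vs 39;
  # c and d are identical scorecards, so only the id breaks their tie
  df <- data.frame(
    id = c("a", "b", "c", "d"),
    conv_mhc2_human = c(58, 39, 20, 20), conv_mhc1_human = c(28, 28, 14, 14),
    conv_sa = c(12, 23, 12, 12), conv_hy = c(9, 9, 9, 9),
    conv_at = c(13, 19, 13, 13), conv_le = c(4, 4, 4, 4),
    conv_rna2 = c(4, 6, 6, 6))
  totals <- category_totals(df)
  expect_equal(totals$grand_total[1], totals$grand_total[2])
  ranked <- rank_candidates(totals)
  expect_equal(ranked$id, c("a", "b", "c", "d"))
  expect_equal(ranked$rank, 1:4)

  # permutation invariance
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    ranked_p <- rank_candidates(category_totals(df[perm, ]))
    expect_equal(ranked_p$id, ranked$id)
  }
  # a single candidate ranks first
  one <- rank_candidates(category_totals(df[1, ]))
  expect_equal(one$rank, 1L)
  expect_error(rank_candidates(df, key = "grand_total"),
               "completeness error")
})

test_that("shortlisting truncates deterministically and idempotently", {
  g <- category_totals(golden_scorecards())
  ranked <- rank_candidates(g)
  top <- shortlist(ranked, 20)
  expect_equal(nrow(top), 20L)
  expect_equal(nrow(shortlist(ranked, 100)), nrow(ranked))
  expect_identical(as.data.frame(shortlist(shortlist(ranked, 5), 5)),
                   as.data.frame(shortlist(ranked, 5)))
  expect_true(all(diff(top$grand_total) <= 0))
})

test_that("reports mirror the published table layouts and are byte-stable", {
  g <- golden_scorecards()
  g$sequence <- g$sequence_bcell
  ranked <- rank_candidates(category_totals(g))
  f1 <- tempfile(); f2 <- tempfile()
  write_report(ranked, "bcell", f1)
  write_report(ranked, "bcell", f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.delim(f1)
  expect_equal(names(tab),
               c("rank", "id", "sequence", "anchor", "modified", "conv_sa",
                 "conv_hy", "conv_at", "conv_le", "conv_rna2", "bcell"))
  expect_equal(tab$bcell, ranked$bcell)

  f3 <- tempfile()
  write_report(ranked, "human_tcell", f3)
  expect_equal(read.delim(f3)$tcell_human, ranked$tcell_human)
  expect_warning(write_report(ranked[0, ], "combined", tempfile()),
                 "header-only")
  expect_error(write_report(g["id"], "bcell", tempfile()),
               "completeness error")
})
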