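make_generic_table <- function(path, scores = c(30, 200, 4500),
                               alleles = c("H-2-Kd", "H-2-Kb", "H-2-Dd"),
                               species = "mouse", mhc_class = "I") {
  df <- data.frame(candidate_id = "c1", allele = alleles,
                   mhc_class = mhc_class, species = species,
                   subpeptide = "YKLVVVGAV", score = scores,
                   score_units = "ic50_nM")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("prediction tables parse with field mapping and schema checks", {
  f <- make_generic_table(tempfile())
  preds <- parse_prediction_table(f, "generic")
  expect_equal(nrow(preds), 3L)
  expect_equal(preds$score, c(30, 200, 4500))
  expect_equal(preds$allele[1], "H-2-Kd")
  expect_equal(preds$row, 1:3)

  # missing required column -> schema error naming it
  df <- read.delim(f)
  df$allele <- NULL
  f2 <- tempfile(); write.table(df, f2, sep = "\t", row.names = FALSE,
                                quote = FALSE)
  expect_error(parse_prediction_table(f2, "generic"), "allele")

  # non-numeric score: error by default, skipped under lenient
  df <- read.delim(f); df$score[2] <- "n/a"
  f3 <- tempfile(); write.table(df, f3, sep = "\t", row.names = FALSE,
                                quote = FALSE)
  expect_error(parse_prediction_table(f3, "generic"), "row")
  expect_warning(ok <- parse_prediction_table(f3, "generic", lenient = TRUE),
                 "skipped")
  expect_equal(nrow(ok), 2L)

  # write -> parse round trip preserves fields
  f4 <- tempfile()
  write_prediction_table(preds, f4)
  again <- parse_prediction_table(f4, "generic")
  expect_equal(again[, 1:7], preds[, 1:7])

  # IEDB-style dialects fill class/units
  iedb <- data.frame(seq_num = "c1", allele = "HLA-A*02:01",
                     peptide = "YKLVVVGAV", ic50 = 12.5)
  f5 <- tempfile(); write.table(iedb, f5, sep = ",", row.names = FALSE,
                                quote = FALSE)
  p5 <- parse_prediction_table(f5, "iedb_mhci", species = "human")
  expect_equal(p5$mhc_class, "I")
  expect_equal(p5$score_units, "ic50_nM")
  expect_equal(p5$score, 12.5)
})

test_that("allele filtering keeps exactly the d-haplotype records for mouse", {
  f <- make_generic_table(tempfile())
  preds <- parse_prediction_table(f, "generic")
  flt <- allele_filter("mouse", "I")
  kept <- filter_alleles(preds, flt)
  expect_equal(kept$allele, c("H-2-Kd", "H-2-Dd"))  # H-2-Kb dropped
  # idempotent; empty allowed set keeps nothing
  expect_identical(filter_alleles(kept, flt), kept)
  flt$allowed_alleles <- character()
  expect_equal(nrow(filter_alleles(preds, flt)), 0L)
  # human default is unrestricted within species/class
  expect_null(allele_filter("human", "II")$allowed_alleles)
})

test_that("aggregation takes the strongest binder and is order-invariant", {
  f <- make_generic_table(tempfile())
  preds <- parse_prediction_table(f, "generic")
  expect_equal(aggregate_best(preds, "c1"), 30)
  expect_equal(aggregate_best(preds[2, ], "c1"), 200)  # single record
  expect_equal(aggregate_best(preds[c(3, 1, 2), ], "c1"), 30)
  expect_equal(aggregate_best(preds, "c1", method = "median"), 200)
  expect_true(all(aggregate_best(preds, "c1") <= preds$score))
  expect_error(aggregate_best(preds, "missing"), "missing-data")
  mixed <- preds; mixed$score_units[2] <- "percentile"
  expect_error(aggregate_best(mixed, "c1"), "unit error")
})

test_that("the toy matrix predictor is a deterministic, flagged stand-in", {
  W0 <- matrix(0, nrow = 3, ncol = 20,
               dimnames = list(NULL, aa_alphabet()))
  p <- toy_matrix_predict("YKLVV", W0, 3)
  expect_equal(p$score, rep(1, 3))  # exp(0) per k-mer
  expect_true(attr(p, "synthetic"))
  expect_equal(p$subpeptide, c("YKL", "KLV", "LVV"))

  # a matrix favoring one k-mer puts it at the aggregated minimum
  W <- matrix(1, nrow = 3, ncol = 20, dimnames = list(NULL, aa_alphabet()))
  W[1, "K"] <- -5; W[2, "L"] <- -5; W[3, "V"] <- -5
  p2 <- toy_matrix_predict("YKLVV", W, 3, candidate_id = "x")
  brute <- setNames(p2$score, p2$subpeptide)
  expect_equal(p2$subpeptide[which.min(p2$score)], "KLV")
  expect_equal(aggregate_best(p2, "x"), unname(min(brute)))

  expect_error(toy_matrix_predict("YK", W, 3), "configuration error")
  expect_error(toy_matrix_predict("YKLVV", W[, 1:10], 3),
               "configuration error")
})
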