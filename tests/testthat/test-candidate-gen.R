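test_that("epitope region extraction honors protein coordinates and bounds", {
  kras <- read_fasta(system.file("extdata", "kras_protein.fasta",
                                 package = "mimorank"))
  region <- extract_region(kras$sequence[1], 4, 18)
  expect_equal(region$sequence, "YKLVVVGAGGVGKSA")
  expect_equal(region$region_start, 4L)
  expect_identical(region$sequence, kras_region()$sequence)

  expect_equal(extract_region("MTEYK", 3, 3)$sequence, "E")
  expect_error(extract_region("YKLVVVGAGGVGKSA", 4, 18), "coordinate error")
  expect_error(extract_region("YKLX", 1, 2), "alphabet error")
})

test_that("anchor and flank mutations rebuild the published mimotopes", {
  wt <- kras_region()
  g12v <- apply_mutation(wt, "G12V")
  g13d <- apply_mutation(wt, "G13D")
  expect_equal(g12v$sequence, "YKLVVVGAVGVGKSA")
  expect_equal(g13d$sequence, "YKLVVVGAGDVGKSA")
  expect_equal(apply_mutation(g13d, "G15Y")$sequence, "YKLVVVGAGDVYKSA")
  expect_equal(apply_mutation(g12v, "V7D")$sequence, "YKLDVVGAVGVGKSA")

  # annotations: codon 12/13 -> anchor, elsewhere -> flank
  m <- apply_mutation(g13d, "G15Y")
  expect_equal(format(m$anchor), "G13D")
  expect_equal(format(m$flank), "G15Y")

  # wrong from-residue guards against coordinate-convention bugs
  expect_error(apply_mutation(wt, "A12V"), "consistency error")
  expect_error(apply_mutation(wt, "G2V"), "coordinate error")

  # self-inverse under the reversed spec
  back <- apply_mutation(g12v, mutation_spec(12, "V", "G"))
  expect_equal(back$sequence, wt$sequence)
})

test_that("library enumeration reproduces the saturation counts", {
  base <- apply_mutation(kras_region(), "G12A")
  lib <- enumerate_library(base)
  expect_equal(nrow(lib$candidates), 240L)  # 12 codons x 20 residues
  expect_equal(nrow(enumerate_library(base, mode = "strict_19")$candidates),
               228L)                        # 12 x 19

  single <- enumerate_library(base, flank_codons = 7, mode = "strict_19")
  expect_equal(nrow(single$candidates), 19L)
  expect_false(any(single$candidates$sequence == base$sequence))

  libs <- enumerate_all()
  expect_length(libs, 7L)
  expect_equal(nrow(candidate_table(libs)), 1680L)

  expect_error(enumerate_library(base, flank_codons = c(4, 12)),
               "configuration error")
  expect_error(enumerate_library(kras_region()), "configuration error")
  expect_error(enumerate_all(character()), "configuration error")
  expect_error(enumerate_all(c("G12A", "G12A")), "configuration error")
})

test_that("every candidate differs from its base at <= 1 flank position", {
  base <- apply_mutation(kras_region(), "G13D")
  lib <- enumerate_library(base)
  base_chars <- strsplit(base$sequence, "")[[1]]
  for (i in seq_len(nrow(lib$candidates))) {
    chars <- strsplit(lib$candidates$sequence[i], "")[[1]]
    diffs <- which(chars != base_chars)
    expect_lte(length(diffs), 1L)
    if (length(diffs))
      expect_true((diffs + base$region_start - 1L) %in% lib$flank_codons)
  }
  # no duplicate (codon, residue) pairs; ids injective
  expect_false(anyDuplicated(
    lib$candidates[, c("flank_codon", "flank_to")]) > 0)
  expect_false(anyDuplicated(lib$candidates$id) > 0)
  # id convention: index + anchor residue suffix
  expect_match(lib$candidates$id, "-D$")
  expect_equal(assign_display_id(lib, 1), "1-D")
})

test_that("enumeration order is deterministic and FASTA output byte-stable", {
  lib1 <- enumerate_library(apply_mutation(kras_region(), "G12C"))
  lib2 <- enumerate_library(apply_mutation(kras_region(), "G12C"))
  expect_identical(lib1$candidates, lib2$candidates)

  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(lib1, f1); write_fasta(lib2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("FASTA round trip preserves identifiers and sequences", {
  lib <- enumerate_library(apply_mutation(kras_region(), "G12S"))
  f <- tempfile(fileext = ".fasta")
  write_fasta(lib, f)
  rec <- read_fasta(f)
  expect_equal(nrow(rec), 240L)
  expect_equal(rec$sequence, lib$candidates$sequence)
  expect_equal(sub("\\|.*", "", rec$id), lib$candidates$id)

  # empty file -> zero records; lowercase -> normalized with warning
  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0L)
  lc <- tempfile()
  writeLines(c(">x", "ykLVV"), lc)
  expect_warning(out <- read_fasta(lc), "lowercase")
  expect_equal(out$sequence, "YKLVV")
})
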