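# Amino-acid propensity scales, transcribed from the original publications.
# Values are keyed by one-letter code; the canonical residue order used for
# deterministic enumeration throughout the package is AA_ALPHABET.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical residues in alphabetical one-letter order. This fixed
#' order defines the deterministic enumeration order of substitution
#' libraries and the column order of weight matrices.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Emini surface accessibility: fractional surface probabilities
# (Emini et al. 1985, J Virol 55:836-839).
.scale_emini <- c(
  A = 0.49, C = 0.26, D = 0.78, E = 0.84, F = 0.42,
  G = 0.48, H = 0.66, I = 0.34, K = 0.97, L = 0.40,
  M = 0.48, N = 0.81, P = 0.75, Q = 0.84, R = 0.95,
  S = 0.65, T = 0.70, V = 0.36, W = 0.51, Y = 0.76)

# Parker hydrophilicity (Parker, Guo & Hodges 1986, Biochemistry 25:5425-5432),
# HPLC-derived hydrophilicity values.
.scale_parker <- c(
  A = 2.1, C = 1.4, D = 10.0, E = 7.8, F = -9.2,
  G = 5.7, H = 2.1, I = -8.0, K = 5.7, L = -9.2,
  M = -4.2, N = 7.0, P = 2.1, Q = 6.0, R = 4.2,
  S = 6.5, T = 5.2, V = -3.7, W = -10.0, Y = -1.9)

# Kolaskar & Tongaonkar antigenic propensity
# (Kolaskar & Tongaonkar 1990, FEBS Lett 276:172-174).
.scale_kolaskar <- c(
  A = 1.064, C = 1.412, D = 0.866, E = 0.851, F = 1.091,
  G = 0.874, H = 1.105, I = 1.152, K = 0.930, L = 1.250,
  M = 1.341, N = 0.776, P = 1.064, Q = 1.015, R = 0.873,
  S = 1.012, T = 0.909, V = 1.383, W = 0.893, Y = 1.161)

# Levitt reverse-turn propensity (Levitt 1978, Biochemistry 17:4277-4285),
# the secondary-structure scale used alongside Parker hydrophilicity for
# linear-epitope propensity.
.scale_levitt <- c(
  A = 0.77, C = 0.81, D = 1.41, E = 0.99, F = 0.59,
  G = 1.64, H = 0.68, I = 0.51, K = 0.96, L = 0.58,
  M = 0.41, N = 1.28, P = 1.91, Q = 0.98, R = 0.88,
  S = 1.32, T = 1.04, V = 0.47, W = 0.76, Y = 1.05)

.scale_registry <- list(
  emini = list(values = .scale_emini,
               source = "Emini et al. (1985) J Virol 55:836-839, fractional surface probability"),
  parker = list(values = .scale_parker,
                source = "Parker, Guo & Hodges (1986) Biochemistry 25:5425-5432, HPLC hydrophilicity"),
  kolaskar = list(values = .scale_kolaskar,
                  source = "Kolaskar & Tongaonkar (1990) FEBS Lett 276:172-174, antigenic propensity"),
  levitt = list(values = .scale_levitt,
                source = "Levitt (1978) Biochemistry 17:4277-4285, reverse-turn propensity"))

#' Retrieve a shipped propensity scale
#'
#' @param name One of `"emini"` (surface accessibility fractional
#'   probabilities), `"parker"` (hydrophilicity), `"kolaskar"`
#'   (Kolaskar-Tongaonkar antigenic propensity), `"levitt"` (reverse-turn
#'   propensity).
#' @return An object of class `propensity_scale`: a named numeric vector of
#'   20 residue values with attributes `name` and `source` (literature
#'   citation).
#' @examples
#' propensity_scale("parker")["D"]  # aspartate, strongly hydrophilic
#' @export
propensity_scale <- function(name = c("emini", "parker", "kolaskar", "levitt")) {
  name <- match.arg(name)
  entry <- .scale_registry[[name]]
  v <- entry$values[aa_alphabet()]
  stopifnot(!anyNA(v), length(v) == 20L)
  structure(v, name = name, source = entry$source, class = "propensity_scale")
}

#' @export
print.propensity_scale <- function(x, ...) {
  cat("Propensity scale:", attr(x, "name"), "\n")
  cat("Source:", attr(x, "source"), "\n")
  print(unclass(structure(as.numeric(x), names = names(x))))
  invisible(x)
}

# Most-frequent codon per amino acid for Lactococcus lactis (AT-rich host
# used for lactococcal expression vectors), assembled from public
# codon-usage compilations. RNA alphabet.
.codon_llactis <- c(
  A = "GCA", C = "UGU", D = "GAU", E = "GAA", F = "UUU",
  G = "GGA", H = "CAU", I = "AUU", K = "AAA", L = "UUA",
  M = "AUG", N = "AAU", P = "CCA", Q = "CAA", R = "CGU",
  S = "UCA", T = "ACA", V = "GUU", W = "UGG", Y = "UAU")

#' Retrieve a shipped codon table for reverse translation
#'
#' A codon table maps each amino acid to a single RNA codon. The default
#' `"llactis"` table uses the most frequent codon per residue for
#' *Lactococcus lactis*, matching the lactococcal expression context in
#' which candidate transcripts are evaluated.
#'
#' @param name Table name; currently `"llactis"`.
#' @return Object of class `codon_table`: named character vector (amino
#'   acid -> RNA codon) with attributes `name` and `source`.
#' @export
codon_table <- function(name = "llactis") {
  name <- match.arg(name, "llactis")
  structure(.codon_llactis[aa_alphabet()],
            name = name,
            source = "Most frequent codon per residue, Lactococcus lactis codon-usage compilations",
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat("Codon table:", attr(x, "name"), "(", attr(x, "source"), ")\n")
  print(unclass(structure(as.character(x), names = names(x))))
  invisible(x)
}

# internal: check a sequence over the 20-letter alphabet
.check_aa <- function(sequence, what = "sequence") {
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), aa_alphabet())
  if (length(bad)) {
    stop(sprintf("alphabet error: %s contains non-canonical residue(s): %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(chars)
}
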