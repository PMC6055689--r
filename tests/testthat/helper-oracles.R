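# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain recursion and explicit summation.

# exhaustive recursive maximum of nested base pairs (no memoization);
# tractable for n <= 12
bf_max_pairs <- function(rna, min_loop = 3L, wobble = TRUE) {
  chars <- strsplit(rna, "")[[1]]
  pairable <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (wobble && ((a == "G" && b == "U") || (a == "U" && b == "G")))
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (pairable(chars[k], chars[j])) {
        v <- 1L + (if (k > i) rec(i, k - 1L) else 0L) +
          (if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L)
        if (v > best) best <- v
      }
    }
    best
  }
  n <- length(chars)
  if (n < 2L) 0L else rec(1L, n)
}

# window mean by explicit per-window summation
bf_window_mean <- function(sequence, scale, window) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  vapply(seq_len(n - window + 1L), function(i) {
    s <- 0
    for (k in i:(i + window - 1L)) s <- s + scale[[chars[k]]]
    s / window
  }, numeric(1))
}

# random RNA strings; len recycles over n
random_rna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len[i], replace = TRUE),
          collapse = ""), "")
}

# representative raw value inside the bin implied by a converted weight
raw_for_weight <- function(parameter, weight) {
  lookup <- list(
    mhc2 = c("58" = 2.0, "39" = 6.0, "20" = 20),
    mhc1 = c("42" = 30, "28" = 200, "14" = 1000),
    sa = c("34" = 2.8, "23" = 2.2, "12" = 1.5),
    hy = c("29" = 4.0, "19" = 3.0, "9" = 2.0),
    at = c("19" = 1.2, "13" = 0.9),
    le = c("12" = 6.0, "8" = 3.0, "4" = 0.2))
  unname(lookup[[parameter]][as.character(weight)])
}
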