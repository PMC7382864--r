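# Independent oracles used across the suite.

# Restricted Damerau-Levenshtein by memoized recursion on prefixes,
# written directly from the operation definitions (insert, delete,
# substitute, adjacent transposition), independent of the package's
# dynamic-programming implementation.
osa_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0L) j else if (j == 0L) i else {
      d <- min(rec(i - 1L, j) + 1L,
               rec(i, j - 1L) + 1L,
               rec(i - 1L, j - 1L) + (a[i] != b[j]))
      if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j]) {
        d <- min(d, rec(i - 2L, j - 2L) + 1L)
      }
      d
    }
    memo[[key]] <- res
    res
  }
  rec(length(a), length(b))
}

# AUC as the Mann-Whitney probability: enumerate every (true, false) pair,
# counting ties as half.
auc_oracle <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

random_string <- function(len, alphabet = LETTERS[1:4]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small noise-free register triple reused across module tests
tiny_population <- function(seed = 42L, ...) {
  cfg <- generator_config(n_cohort = 150L, n_births = 80L,
                          overlap_fraction = 0.5, typo_rate = 0,
                          missing_mother_dob_rate = 0,
                          municipality_mismatch_rate = 0,
                          age_error_rate = 0, covariate_missing_rate = 0.05,
                          seed = seed, ...)
  generate_population(cfg)
}
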