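#' String and date comparators for record linkage
#'
#' Pairwise attribute comparators used throughout the linkage pipeline:
#' [jaro()] and [jaro_winkler()] for person names, [damerau_levenshtein()]
#' (restricted / optimal-string-alignment variant) for the fuzzy blocking
#' filter, and [hamming_date()] for fixed-width compact dates. All
#' normalized similarities lie in `[0, 1]`, are symmetric in their
#' arguments, and score 1 for identical inputs.
#'
#' @name comparators
NULL

#' Jaro string similarity
#'
#' Mean of `m/|s1|`, `m/|s2|` and `(m - t)/m`, where `m` counts characters
#' common to both strings within a window of `floor(max(|s1|,|s2|)/2) - 1`
#' positions and `t` is half the number of matched characters that appear
#' in a different order. Returns 0 when there are no common characters or
#' exactly one string is empty; two empty strings compare as identical.
#'
#' @param s1,s2 Character vectors (recycled to a common length).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro("MARTHA", "MARHTA") # 0.9444...
#' @export
jaro <- function(s1, s2) {
  .jaro_cpp(as.character(s1), as.character(s2))
}

#' Jaro-Winkler string similarity
#'
#' Jaro similarity with a bonus for a shared prefix:
#' `jaro + l * prefix_scale * (1 - jaro)` with `l` the common-prefix length
#' capped at `max_prefix`. Always at least the plain Jaro value.
#'
#' @inheritParams jaro
#' @param prefix_scale Prefix bonus scale in `[0, 0.25]` (default 0.1).
#' @param max_prefix Maximum prefix length receiving the bonus (default 4).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA") # 0.9611...
#' @export
jaro_winkler <- function(s1, s2, prefix_scale = 0.1, max_prefix = 4L) {
  if (!is.numeric(prefix_scale) || length(prefix_scale) != 1L ||
      is.na(prefix_scale) || prefix_scale < 0 || prefix_scale > 0.25) {
    stop("`prefix_scale` must be a single value in [0, 0.25]", call. = FALSE)
  }
  .jaro_winkler_cpp(as.character(s1), as.character(s2),
                    prefix_scale, as.integer(max_prefix))
}

#' Damerau-Levenshtein edit distance (restricted variant)
#'
#' Minimum number of insertions, deletions, substitutions and adjacent
#' transpositions converting one string into the other, computed as the
#' optimal string alignment (restricted) variant: no substring is edited
#' more than once, so e.g. `damerau_levenshtein("CA", "ABC")` is 3, not
#' the 2 of the unrestricted distance.
#'
#' @inheritParams jaro
#' @return Integer vector of edit distances.
#' @seealso [dl_similarity()] for the normalized form.
#' @export
damerau_levenshtein <- function(s1, s2) {
  .osa_cpp(as.character(s1), as.character(s2))
}

#' Normalized Damerau-Levenshtein similarity
#'
#' `1 - d / max(|s1|, |s2|)`; defined as 1 when both strings are empty.
#'
#' @inheritParams jaro
#' @return Numeric vector in `[0, 1]`.
#' @export
dl_similarity <- function(s1, s2) {
  s1 <- as.character(s1)
  s2 <- as.character(s2)
  d <- .osa_cpp(s1, s2)
  n <- length(d)
  w <- pmax(nchar(rep_len(s1, n)), nchar(rep_len(s2, n)))
  ifelse(w == 0, 1, 1 - d / w)
}

#' Hamming distance between fixed-width compact dates
#'
#' Count of differing positions between two equal-width strings. Dates are
#' compared in their 8-digit compact form (`YYYYMMDD`); a width mismatch is
#' an error, never a silent truncation.
#'
#' @param d1,d2 Character vectors of equal-width strings.
#' @return Integer vector of position counts.
#' @seealso [date_similarity()] for the normalized form.
#' @export
hamming_date <- function(d1, d2) {
  .hamming_cpp(as.character(d1), as.character(d2))
}

#' Normalized date similarity
#'
#' `1 - hamming/width` on the 8-digit compact date form.
#'
#' @inheritParams hamming_date
#' @return Numeric vector in `[0, 1]`.
#' @export
date_similarity <- function(d1, d2) {
  d1 <- as.character(d1)
  d2 <- as.character(d2)
  h <- .hamming_cpp(d1, d2)
  w <- nchar(rep_len(d1, length(h)))
  ifelse(w == 0, 1, 1 - h / w)
}

#' Compact 8-digit form of a date
#'
#' @param x `Date` vector or ISO-8601 (`YYYY-MM-DD`) character vector.
#' @return Character vector in `YYYYMMDD` form (`NA` preserved).
#' @export
compact_date <- function(x) {
  if (!inherits(x, "Date")) x <- as.Date(x)
  format(x, "%Y%m%d")
}
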