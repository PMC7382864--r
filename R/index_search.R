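#' Build an inverted index over the cohort register
#'
#' Blocking structure for candidate retrieval: postings lists map each
#' (field, token) to the sorted cohort row numbers carrying it. Indexed
#' fields are the full standardized name (as a single key), the individual
#' name tokens, the municipality code, the state code and the compact date
#' of birth. Records missing a field are simply absent from that field's
#' postings. The build is single-pass and deterministic.
#'
#' @param cohort data.frame with columns `person_id`, `name`, `dob`,
#'   `municipality`, `state` (names already standardized).
#' @return An `inverted_index` object.
#' @export
build_index <- function(cohort) {
  if (anyDuplicated(cohort$person_id)) {
    stop("duplicate cohort person_id: ",
         cohort$person_id[duplicated(cohort$person_id)][1], call. = FALSE)
  }
  rows <- seq_len(nrow(cohort))
  post_env <- function(keys, rows) {
    keep <- !is.na(keys) & nzchar(keys)
    list2env(lapply(split(rows[keep], keys[keep]), sort), hash = TRUE,
             size = max(length(unique(keys[keep])), 1L))
  }
  tok <- name_tokens(cohort$name)
  tok_rows <- rep(rows, lengths(tok))
  tok_keys <- unlist(tok)
  dup <- duplicated(paste(tok_rows, tok_keys))  # one posting per (row, token)
  idx <- list(
    postings = list(
      name_full = post_env(cohort$name, rows),
      name_token = post_env(tok_keys[!dup], tok_rows[!dup]),
      municipality = post_env(cohort$municipality, rows),
      state = post_env(cohort$state, rows),
      dob = post_env(ifelse(is.na(cohort$dob), NA_character_,
                            gsub("-", "", cohort$dob, fixed = TRUE)), rows)
    ),
    cohort = cohort,
    n = nrow(cohort)
  )
  class(idx) <- "inverted_index"
  idx
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("inverted_index:", x$n, "records;",
      length(ls(x$postings$name_token)), "name tokens\n")
  invisible(x)
}

lookup <- function(idx, field, key) {
  if (is.na(key) || !nzchar(key)) return(integer(0))
  e <- idx$postings[[field]]
  if (exists(key, envir = e, inherits = FALSE)) get(key, envir = e) else integer(0)
}

# supplied probe attributes; NA / empty fields count as not supplied
probe_attrs <- function(probe) {
  a <- list()
  if (!is.null(probe$name) && !is.na(probe$name) && nzchar(probe$name)) {
    a$name_full <- probe$name
  }
  if (!is.null(probe$municipality) && !is.na(probe$municipality)) {
    a$municipality <- probe$municipality
  }
  if (!is.null(probe$dob) && !is.na(probe$dob)) {
    a$dob <- gsub("-", "", probe$dob, fixed = TRUE)
  }
  a
}

#' Exact-tier query
#'
#' Intersection of the postings of every supplied probe attribute: the
#' full name (equality of the ordered token sequence), the municipality
#' code, and — when the probe carries it — the mother's date of birth.
#'
#' @param idx An [build_index()] result.
#' @param probe List with `name`, `municipality` and optionally `dob`
#'   (ISO date or `NA`).
#' @return Sorted integer vector of cohort row numbers.
#' @export
query_exact <- function(idx, probe) {
  a <- probe_attrs(probe)
  if (length(a) == 0L) return(integer(0))
  sets <- mapply(function(f, k) lookup(idx, f, k), names(a), a,
                 SIMPLIFY = FALSE)
  Reduce(intersect, sets)
}

#' Semi-fuzzy-tier query
#'
#' Candidates agreeing exactly on all supplied attributes but one: the
#' union over leave-one-attribute-out exact intersections, minus the
#' exact-tier results. Empty when the probe supplies fewer than two
#' attributes.
#'
#' @inheritParams query_exact
#' @return Sorted integer vector of cohort row numbers.
#' @export
query_semi_fuzzy <- function(idx, probe) {
  a <- probe_attrs(probe)
  if (length(a) < 2L) return(integer(0))
  out <- integer(0)
  for (drop in seq_along(a)) {
    rest <- a[-drop]
    sets <- mapply(function(f, k) lookup(idx, f, k), names(rest), rest,
                   SIMPLIFY = FALSE)
    out <- union(out, Reduce(intersect, sets))
  }
  sort(setdiff(out, query_exact(idx, probe)))
}

#' Fuzzy-tier query
#'
#' Candidates sharing at least one name token with the probe, ranked by
#' shared-token count, then normalized Damerau-Levenshtein similarity of
#' the full names, then cohort row (ascending) for determinism. Candidates
#' whose normalized similarity is not above `dl_floor` are removed.
#'
#' @inheritParams query_exact
#' @param dl_floor Minimum (exclusive) normalized Damerau-Levenshtein
#'   similarity for a fuzzy candidate to be retained (default 0.5).
#' @return data.frame with columns `row`, `shared_tokens`, `dl_sim`, ranked.
#' @export
query_fuzzy <- function(idx, probe, dl_floor = 0.5) {
  toks <- unique(name_tokens(probe$name)[[1]])
  hits <- unlist(lapply(toks, function(t) lookup(idx, "name_token", t)))
  if (length(hits) == 0L) {
    return(data.frame(row = integer(0), shared_tokens = integer(0),
                      dl_sim = numeric(0)))
  }
  shared <- table(hits)
  row <- as.integer(names(shared))
  sim <- dl_similarity(probe$name, idx$cohort$name[row])
  keep <- sim > dl_floor
  out <- data.frame(row = row[keep],
                    shared_tokens = as.integer(shared)[keep],
                    dl_sim = sim[keep])
  out[order(-out$shared_tokens, -out$dl_sim, out$row), , drop = FALSE]
}

#' Retrieve the top-k candidates for a probe record
#'
#' Three-tier cascade: exact, then semi-fuzzy, then fuzzy. Duplicates keep
#' their highest tier; the concatenated list is truncated to the `k` best
#' candidates.
#'
#' @inheritParams query_fuzzy
#' @param k Maximum number of candidates to return (default 1000).
#' @return data.frame with columns `row`, `tier`
#'   (`exact`/`semi_fuzzy`/`fuzzy`) and `retrieval_score` (shared-token
#'   count for the fuzzy tier, `NA` otherwise).
#' @export
retrieve_candidates <- function(idx, probe, k = 1000L, dl_floor = 0.5) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  ex <- query_exact(idx, probe)
  sf <- query_semi_fuzzy(idx, probe)
  fz <- query_fuzzy(idx, probe, dl_floor = dl_floor)
  out <- data.frame(
    row = c(ex, sf, fz$row),
    tier = rep(c("exact", "semi_fuzzy", "fuzzy"),
               c(length(ex), length(sf), nrow(fz))),
    retrieval_score = c(rep(NA_real_, length(ex) + length(sf)), fz$dl_sim),
    stringsAsFactors = FALSE
  )
  out <- out[!duplicated(out$row), , drop = FALSE]
  utils::head(out, k)
}

#' Persist an inverted index to a plain-text layout
#'
#' Versioned header line (`birthlink-index v1 <n>`), then one
#' tab-separated line per posting: field, token, comma-separated sorted
#' row numbers, with lines sorted by field then token. The cohort
#' register itself is not stored; [read_index()] re-attaches it.
#'
#' @param idx An [build_index()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index <- function(idx, path) {
  stopifnot(inherits(idx, "inverted_index"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("birthlink-index v1 %d", idx$n), con)
  for (field in sort(names(idx$postings))) {
    e <- idx$postings[[field]]
    for (key in sort(ls(e))) {
      writeLines(paste(field, key,
                       paste(get(key, e), collapse = ","), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Load a persisted inverted index
#'
#' @param path File written by [write_index()].
#' @param cohort The cohort register the index was built from (row order
#'   must match; checked against the header's record count).
#' @return An `inverted_index`.
#' @export
read_index <- function(path, cohort) {
  lines <- readLines(path, warn = FALSE)
  hd <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(hd) != 3L || hd[1] != "birthlink-index" || hd[2] != "v1") {
    stop("not a birthlink index file: ", path, call. = FALSE)
  }
  if (as.integer(hd[3]) != nrow(cohort)) {
    stop("index was built over ", hd[3], " records but the cohort has ",
         nrow(cohort), call. = FALSE)
  }
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  fields <- vapply(parts, `[`, character(1), 1L)
  idx <- list(postings = list(), cohort = cohort, n = nrow(cohort))
  for (field in unique(fields)) {
    sel <- parts[fields == field]
    keys <- vapply(sel, `[`, character(1), 2L)
    vals <- lapply(sel, function(p)
      as.integer(strsplit(p[3], ",", fixed = TRUE)[[1]]))
    idx$postings[[field]] <- list2env(stats::setNames(vals, keys),
                                      hash = TRUE)
  }
  class(idx) <- "inverted_index"
  idx
}
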