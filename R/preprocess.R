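#' Standardize a recorded name
#'
#' Uppercases, transliterates accented letters to their unaccented forms,
#' replaces punctuation (any character that is not a letter, digit or
#' space) with a space, collapses runs of whitespace and trims. Middle
#' initials, prefixes and suffixes are kept as recorded: only the
#' characters change, never the tokens. Idempotent.
#'
#' Inputs that are empty after cleaning (e.g. punctuation-only strings)
#' come back as `""` so callers can flag rather than silently drop them.
#'
#' @param raw Character vector of recorded names.
#' @return Character vector of standardized names.
#' @examples
#' standardize_name("  maria.  da-silva ") # "MARIA DA SILVA"
#' @export
standardize_name <- function(raw) {
  x <- toupper(as.character(raw))
  x <- fold_accents(x)
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Accent folding for the Latin-1 letters seen in Brazilian registers.
fold_accents <- function(x) {
  from <- "ÁÀÂÃÄÉÈÊËÍÌÎÏÓÒÔÕÖÚÙÛÜÇÑ"
  to <- "AAAAAEEEEIIIIOOOOOUUUUCN"
  chartr(from, to, x)
}

#' Split a standardized name into tokens
#' @param name Character vector of standardized names.
#' @return List of character vectors of tokens.
#' @export
name_tokens <- function(name) {
  strsplit(as.character(name), " ", fixed = TRUE)
}

#' Default invalid-name markers
#'
#' Markers for the placeholder strings that clinical staff record instead
#' of a real name: abbreviations of "newborn", "unknown", "ignored" and the
#' like. Shipped as a plain-text default; supply your own file to extend it.
#'
#' @param path Optional path to a newline-delimited marker file.
#' @return Character vector of standardized markers (single tokens or
#'   multi-word phrases).
#' @export
default_stop_terms <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "stop_terms.txt", package = "birthlink",
                        mustWork = TRUE)
  }
  standardize_name(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Reference lexicon of plausible name tokens
#'
#' Union of the bundled given-name and surname lists plus the Portuguese
#' connective particles (DA, DE, DO, DAS, DOS, E). A stand-in for a
#' national reference list of names.
#'
#' @param given,surnames Optional paths to newline-delimited token files.
#' @return Character vector of valid tokens (no duplicates).
#' @export
default_lexicon <- function(given = NULL, surnames = NULL) {
  if (is.null(given)) {
    given <- system.file("extdata", "given_names.txt", package = "birthlink",
                         mustWork = TRUE)
  }
  if (is.null(surnames)) {
    surnames <- system.file("extdata", "surnames.txt", package = "birthlink",
                            mustWork = TRUE)
  }
  toks <- c(readLines(given, warn = FALSE), readLines(surnames, warn = FALSE),
            "DA", "DE", "DO", "DAS", "DOS", "E")
  unique(standardize_name(toks))
}

#' Screen standardized names against a lexicon and invalid markers
#'
#' Routes each name to one of three verdicts: `invalid` when it is empty or
#' contains an invalid marker (single-token markers are matched per token,
#' multi-word markers as a phrase); `needs_review` when at least one token
#' is absent from the lexicon but no marker matches; `valid` otherwise.
#' Deterministic and order-independent.
#'
#' @param names Character vector of standardized names.
#' @param lexicon Character vector of valid name tokens.
#' @param stop_terms Character vector of invalid markers.
#' @return A data.frame with columns `name`, `status`
#'   (`valid`/`invalid`/`needs_review`) and `reason` (non-empty whenever
#'   `status == "invalid"`).
#' @export
screen_invalid_names <- function(names,
                                 lexicon = default_lexicon(),
                                 stop_terms = default_stop_terms()) {
  if (length(lexicon) == 0L) stop("`lexicon` must be non-empty", call. = FALSE)
  if (length(stop_terms) == 0L) stop("`stop_terms` must be non-empty", call. = FALSE)
  names <- as.character(names)
  single <- stop_terms[!grepl(" ", stop_terms, fixed = TRUE)]
  phrases <- stop_terms[grepl(" ", stop_terms, fixed = TRUE)]
  toks <- name_tokens(names)
  status <- character(length(names))
  reason <- character(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    tk <- toks[[i]]
    if (is.na(nm) || !nzchar(nm)) {
      status[i] <- "invalid"
      reason[i] <- "empty after standardization"
      next
    }
    hit <- tk[tk %in% single]
    if (length(hit) == 0L && length(phrases)) {
      padded <- paste0(" ", nm, " ")
      hit <- phrases[vapply(phrases, function(p)
        grepl(paste0(" ", p, " "), padded, fixed = TRUE), logical(1))]
    }
    if (length(hit)) {
      status[i] <- "invalid"
      reason[i] <- paste0("invalid marker: ", hit[1])
    } else if (!all(tk %in% lexicon)) {
      status[i] <- "needs_review"
      reason[i] <- paste0("tokens not in lexicon: ",
                          paste(setdiff(tk, lexicon), collapse = ", "))
    } else {
      status[i] <- "valid"
      reason[i] <- ""
    }
  }
  data.frame(name = names, status = status, reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply clerical-review decisions to screened records
#'
#' The clerical review is modeled as a decisions table mapping each
#' `needs_review` name to `keep` or `exclude`. Records whose name verdict
#' is `invalid`, or reviewed as `exclude`, are removed; the rest pass to
#' linkage. Every `needs_review` name must be decided.
#'
#' @param records data.frame containing the name column to screen on.
#' @param name_col Name of the column holding standardized names.
#' @param verdicts Output of [screen_invalid_names()] for
#'   `records[[name_col]]`.
#' @param decisions data.frame with columns `name` and `decision`
#'   (`keep`/`exclude`), or `NULL` when no name needs review.
#' @return List with `records` (kept rows) and `audit` (data.frame of
#'   excluded names with reasons, plus verdict counts as attributes).
#' @export
apply_review_decisions <- function(records, name_col, verdicts,
                                   decisions = NULL) {
  stopifnot(nrow(verdicts) == nrow(records))
  review <- unique(verdicts$name[verdicts$status == "needs_review"])
  if (length(review)) {
    if (is.null(decisions)) {
      stop("names need review but no decisions were supplied: ",
           paste(utils::head(review, 5L), collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(review, decisions$name)
    if (length(missing)) {
      stop("no review decision for: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    bad <- setdiff(decisions$decision, c("keep", "exclude"))
    if (length(bad)) stop("unknown decision value: ", bad[1], call. = FALSE)
  }
  drop <- verdicts$status == "invalid"
  why <- ifelse(drop, verdicts$reason, "")
  if (length(review) && !is.null(decisions)) {
    excl <- decisions$name[decisions$decision == "exclude"]
    hit <- verdicts$status == "needs_review" & verdicts$name %in% excl
    drop <- drop | hit
    why[hit] <- "excluded at clerical review"
  }
  audit <- data.frame(name = verdicts$name[drop], reason = why[drop],
                      stringsAsFactors = FALSE)
  attr(audit, "counts") <- c(table(factor(verdicts$status,
    levels = c("valid", "invalid", "needs_review"))))
  list(records = records[!drop, , drop = FALSE], audit = audit)
}
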