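#' Default attribute weights for pair scoring
#'
#' Discriminatory-power weights: mother's name 1, maternal age or date of
#' birth 1, municipality of residence 0.16, state 0.008. The combined
#' score of a pair is the weighted mean of the per-attribute similarities
#' over the attributes available on both records, so it stays in `[0, 1]`
#' whatever the missingness pattern.
#'
#' @return Named numeric vector of weights.
#' @export
default_weights <- function() {
  c(name = 1, mother_dob_or_age = 1, municipality = 0.16, state = 0.008)
}

# completed calendar years between two ISO/Date values (vectorized)
completed_years <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  n <- max(length(from), length(to))
  from <- rep_len(from, n); to <- rep_len(to, n)
  fy <- as.integer(format(from, "%Y")); ty <- as.integer(format(to, "%Y"))
  fmd <- format(from, "%m%d"); tmd <- format(to, "%m%d")
  ty - fy - as.integer(tmd < fmd)
}

#' Derive maternal age from the two dates of birth
#'
#' Completed calendar years between the mother's and the child's dates of
#' birth: subtract the years, minus one when the child's month/day precedes
#' the mother's birthday. Exact calendar arithmetic (never division by
#' 365.25), because the downstream consistency filter requires exact
#' agreement with the recorded age.
#'
#' @param child_dob,mother_dob Dates (`Date` or ISO-8601 text).
#' @return Integer vector of ages in completed years.
#' @export
derive_maternal_age <- function(child_dob, mother_dob) {
  age <- completed_years(mother_dob, child_dob)
  bad <- !is.na(age) & age <= 0 &
    as.Date(rep_len(as.Date(mother_dob), length(age))) >=
      as.Date(rep_len(as.Date(child_dob), length(age)))
  if (any(bad)) {
    stop("mother_dob on or after child_dob: impossible record", call. = FALSE)
  }
  age
}

#' Exact-age consistency filter
#'
#' For births without a usable mother's date of birth, candidates are kept
#' only when the age derived from the candidate's date of birth and the
#' child's date of birth equals the recorded maternal age exactly. A
#' missing recorded age skips the filter (all candidates pass).
#'
#' @param candidate_dob Candidate cohort dates of birth.
#' @param child_dob The birth record's child date of birth (scalar).
#' @param recorded_age Recorded maternal age in completed years (scalar,
#'   may be `NA`).
#' @return Logical vector: keep each candidate?
#' @export
age_consistency_filter <- function(candidate_dob, child_dob, recorded_age) {
  if (is.na(recorded_age)) return(rep(TRUE, length(candidate_dob)))
  derived <- completed_years(candidate_dob, child_dob)
  !is.na(derived) & derived == as.integer(recorded_age)
}

# Score one birth against a set of cohort rows. `use_dob` selects the
# comparison route for the age/DOB attribute; under the age route the
# candidates are assumed to have passed the consistency filter, and the
# attribute contributes similarity 1 (or is dropped when the recorded age
# itself is missing).
score_against <- function(birth, cohort_rows, weights, use_dob,
                          age_gated = TRUE) {
  ncand <- nrow(cohort_rows)
  s_name <- jaro_winkler(birth$mother_name, cohort_rows$name)
  w_name <- rep(weights[["name"]], ncand)

  if (use_dob) {
    s_age <- rep(NA_real_, ncand)
    ok <- !is.na(cohort_rows$dob)
    if (any(ok)) {
      s_age[ok] <- date_similarity(compact_date(birth$mother_dob),
                                   compact_date(cohort_rows$dob[ok]))
    }
  } else if (!is.na(birth$mother_age) && age_gated) {
    s_age <- rep(1, ncand)
  } else {
    s_age <- rep(NA_real_, ncand)
  }
  w_age <- ifelse(is.na(s_age), 0, weights[["mother_dob_or_age"]])

  s_muni <- ifelse(is.na(birth$municipality) | is.na(cohort_rows$municipality),
                   NA_real_,
                   as.numeric(birth$municipality == cohort_rows$municipality))
  w_muni <- ifelse(is.na(s_muni), 0, weights[["municipality"]])
  s_state <- ifelse(is.na(birth$state) | is.na(cohort_rows$state), NA_real_,
                    as.numeric(birth$state == cohort_rows$state))
  w_state <- ifelse(is.na(s_state), 0, weights[["state"]])

  wsum <- w_name + w_age + w_muni + w_state
  if (any(wsum == 0)) stop("pair with no comparable attribute", call. = FALSE)
  num <- s_name * w_name +
    ifelse(is.na(s_age), 0, s_age) * w_age +
    ifelse(is.na(s_muni), 0, s_muni) * w_muni +
    ifelse(is.na(s_state), 0, s_state) * w_state
  data.frame(sim_name = s_name, sim_dob_age = s_age, sim_municipality = s_muni,
             sim_state = s_state, score = num / wsum)
}

#' Score one birth record against candidate cohort rows
#'
#' Weighted similarity: Jaro-Winkler on the mother's name, normalized
#' Hamming date similarity on the mother's date of birth (when the birth
#' record carries one), binary code equality on municipality and state.
#' Births without a usable mother's date of birth take the age route: the
#' exact-age consistency filter has gated the candidates, and the age
#' attribute contributes similarity 1 for the survivors (or is dropped
#' entirely when the recorded age is missing). The combined score is the
#' weight-normalized mean over comparable attributes.
#'
#' @param birth Single-row data.frame (one birth record).
#' @param candidates data.frame of candidate cohort rows (columns `name`,
#'   `dob`, `municipality`, `state`, `person_id`).
#' @param weights Named weights as in [default_weights()].
#' @param era One of `"auto"` (date-of-birth route whenever the birth
#'   record has a mother DOB), `"dob"` (same) or `"age"` (ignore mother
#'   DOB entirely, as in the years before it was collected).
#' @return `candidates` augmented with per-attribute similarities and
#'   `score`.
#' @export
score_pairs <- function(birth, candidates, weights = default_weights(),
                        era = c("auto", "dob", "age")) {
  era <- match.arg(era)
  use_dob <- era != "age" && !is.na(birth$mother_dob)
  cbind(candidates,
        score_against(birth, candidates, weights, use_dob = use_dob))
}

#' Globally resolve scored pairs into one-to-one links
#'
#' Greedy global assignment: all scored pairs are sorted by score
#' (descending), then birth id, then cohort id (both ascending, as the
#' deterministic tie-break); a pair is accepted iff neither its birth nor
#' its cohort record is already taken. Births left without an accepted
#' pair get a null cohort id. No cohort record is ever assigned twice.
#'
#' @param pairs data.frame with columns `birth_id`, `person_id`, `score`.
#' @param birth_ids All birth ids that should appear in the output (births
#'   with no scored candidate are kept with a null assignment).
#' @return data.frame `birth_id`, `cohort_id` (`NA` when unmatched),
#'   `score`.
#' @export
assign_best_links <- function(pairs, birth_ids = unique(pairs$birth_id)) {
  out_b <- character(0); out_c <- character(0); out_s <- numeric(0)
  if (nrow(pairs)) {
    o <- order(-pairs$score, pairs$birth_id, pairs$person_id)
    pairs <- pairs[o, , drop = FALSE]
    taken_c <- new.env(hash = TRUE)
    taken_b <- new.env(hash = TRUE)
    for (i in seq_len(nrow(pairs))) {
      b <- pairs$birth_id[i]; p <- pairs$person_id[i]
      if (exists(b, taken_b, inherits = FALSE) ||
          exists(p, taken_c, inherits = FALSE)) next
      assign(b, TRUE, taken_b); assign(p, TRUE, taken_c)
      out_b <- c(out_b, b); out_c <- c(out_c, p); out_s <- c(out_s, pairs$score[i])
    }
  }
  left <- setdiff(birth_ids, out_b)
  res <- data.frame(
    birth_id = c(out_b, left),
    cohort_id = c(out_c, rep(NA_character_, length(left))),
    score = c(out_s, rep(NA_real_, length(left))),
    stringsAsFactors = FALSE
  )
  res[order(res$birth_id), , drop = FALSE]
}

#' Run retrieval, filtering and scoring over a births register
#'
#' For each birth: retrieve up to `k` candidates from the inverted index
#' (the probe uses name + municipality, plus mother DOB when present and
#' the era mode allows it), apply the exact-age consistency filter on the
#' age route, score the survivors, then resolve all pairs into one-to-one
#' assignments with [assign_best_links()].
#'
#' @param births Births register (standardized names).
#' @param idx [build_index()] over the cohort register.
#' @param weights Attribute weights.
#' @param k Candidates retrieved per birth.
#' @param dl_floor Fuzzy-tier name-similarity floor.
#' @param era Era mode, see [score_pairs()].
#' @return List with `pairs` (all scored pairs) and `assignments`
#'   (pre-threshold one-to-one decisions).
#' @export
link_records <- function(births, idx, weights = default_weights(),
                         k = 1000L, dl_floor = 0.5,
                         era = c("auto", "dob", "age")) {
  era <- match.arg(era)
  all_pairs <- vector("list", nrow(births))
  for (i in seq_len(nrow(births))) {
    b <- births[i, , drop = FALSE]
    use_dob <- era != "age" && !is.na(b$mother_dob)
    probe <- list(name = b$mother_name, municipality = b$municipality,
                  dob = if (use_dob) b$mother_dob else NA_character_)
    cand <- retrieve_candidates(idx, probe, k = k, dl_floor = dl_floor)
    if (nrow(cand) == 0L) next
    rows <- idx$cohort[cand$row, , drop = FALSE]
    if (!use_dob) {
      keep <- age_consistency_filter(rows$dob, b$child_dob, b$mother_age)
      rows <- rows[keep, , drop = FALSE]
      cand <- cand[keep, , drop = FALSE]
      if (nrow(rows) == 0L) next
    }
    sc <- score_pairs(b, rows, weights = weights, era = era)
    all_pairs[[i]] <- data.frame(
      birth_id = b$birth_id, person_id = rows$person_id, tier = cand$tier,
      sc[, c("sim_name", "sim_dob_age", "sim_municipality", "sim_state",
             "score")],
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, all_pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(birth_id = character(0), person_id = character(0),
                        tier = character(0), sim_name = numeric(0),
                        sim_dob_age = numeric(0), sim_municipality = numeric(0),
                        sim_state = numeric(0), score = numeric(0))
  }
  list(pairs = pairs,
       assignments = assign_best_links(pairs, birth_ids = births$birth_id))
}

#' Locate the offspring record of a linked mother
#'
#' After a mother link is established, searches her family in the cohort
#' for the unique member with the child's date of birth and sex. Returns a
#' null id when none matches and flags (without assigning) the ambiguous
#' case of same-sex twins sharing a date of birth.
#'
#' @param assignments Mother assignments from [link_records()] (or the
#'   post-threshold decisions).
#' @param births Births register.
#' @param cohort Cohort register.
#' @return data.frame `birth_id`, `offspring_id` (`NA` when absent or
#'   ambiguous), `ambiguous` (logical).
#' @export
find_offspring <- function(assignments, births, cohort) {
  linked <- assignments[!is.na(assignments$cohort_id), , drop = FALSE]
  fam_of <- cohort$family_id[match(linked$cohort_id, cohort$person_id)]
  bi <- match(linked$birth_id, births$birth_id)
  off <- rep(NA_character_, nrow(linked))
  amb <- rep(FALSE, nrow(linked))
  for (i in seq_len(nrow(linked))) {
    members <- which(cohort$family_id == fam_of[i] &
                     cohort$person_id != linked$cohort_id[i] &
                     !is.na(cohort$dob) &
                     cohort$dob == births$child_dob[bi[i]] &
                     cohort$sex == births$child_sex[bi[i]])
    if (length(members) == 1L) {
      off[i] <- cohort$person_id[members]
    } else if (length(members) > 1L) {
      amb[i] <- TRUE
    }
  }
  data.frame(birth_id = linked$birth_id, offspring_id = off, ambiguous = amb,
             stringsAsFactors = FALSE)
}
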