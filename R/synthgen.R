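#' Configuration for the synthetic register generator
#'
#' Parameterizes a pair of synthetic registers: a births register with
#' maternal identifying attributes (emulating a live-birth information
#' system) and a cohort register (emulating a social-registry baseline),
#' together with a ground-truth table of mother-baby matches. Error rates
#' control the corruption applied to maternal attributes on the birth side,
#' so downstream blocking, scoring and evaluation can be exercised at any
#' noise level, including the regime where the mother's date of birth is
#' structurally absent from the births register.
#'
#' @param n_cohort Number of cohort adults (>= 1).
#' @param n_births Number of birth records (>= 1).
#' @param overlap_fraction Proportion in `[0, 1]` of births whose true
#'   mother exists in the cohort; the truth table carries exactly
#'   `round(overlap_fraction * n_births)` non-null mother ids.
#' @param typo_rate Per-name probability in `[0, 1]` that typographical
#'   errors are injected into the recorded mother name.
#' @param missing_mother_dob_rate Probability in `[0, 1]` that a birth
#'   record lacks the mother's date of birth (the pre-availability regime).
#' @param municipality_mismatch_rate Probability in `[0, 1]` that the
#'   municipality (and hence possibly state) of residence differs between
#'   the two registers.
#' @param age_error_rate Probability in `[0, 1]` that the recorded maternal
#'   age is perturbed by one year from the age derived from true dates of
#'   birth, exercising the exact-age consistency filter's failure mode.
#' @param covariate_missing_rate Per-covariate probability in `[0, 1]` of a
#'   `Missing` category value.
#' @param year_range Inclusive integer span of birth years, e.g.
#'   `c(2010, 2015)`.
#' @param seed Integer seed; identical config and seed reproduce the
#'   registers byte for byte.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_cohort = 1000L,
                             n_births = 600L,
                             overlap_fraction = 0.6,
                             typo_rate = 0.05,
                             missing_mother_dob_rate = 0.2,
                             municipality_mismatch_rate = 0.05,
                             age_error_rate = 0.05,
                             covariate_missing_rate = 0.05,
                             year_range = c(2010L, 2015L),
                             seed = 1L) {
  cfg <- list(n_cohort = as.integer(n_cohort), n_births = as.integer(n_births),
              overlap_fraction = overlap_fraction, typo_rate = typo_rate,
              missing_mother_dob_rate = missing_mother_dob_rate,
              municipality_mismatch_rate = municipality_mismatch_rate,
              age_error_rate = age_error_rate,
              covariate_missing_rate = covariate_missing_rate,
              year_range = as.integer(year_range), seed = as.integer(seed))
  for (fld in c("n_cohort", "n_births")) {
    if (is.na(cfg[[fld]]) || cfg[[fld]] < 1L) {
      stop(sprintf("`%s` must be a count >= 1", fld), call. = FALSE)
    }
  }
  for (fld in c("overlap_fraction", "typo_rate", "missing_mother_dob_rate",
                "municipality_mismatch_rate", "age_error_rate",
                "covariate_missing_rate")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", fld), call. = FALSE)
    }
  }
  if (length(cfg$year_range) != 2L || any(is.na(cfg$year_range)) ||
      cfg$year_range[1] > cfg$year_range[2]) {
    stop("`year_range` must be an inclusive integer span c(first, last)",
         call. = FALSE)
  }
  if (is.na(cfg$seed)) stop("`seed` must be an integer", call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

# Administrative geography: three synthetic two-digit state codes with ten
# seven-digit municipality codes each (IBGE-like shape).
synthetic_municipalities <- function() {
  states <- c("26", "29", "35")
  data.frame(
    state = rep(states, each = 10L),
    municipality = paste0(rep(states, each = 10L),
                          sprintf("%05d", rep(1:10, times = 3L))),
    stringsAsFactors = FALSE
  )
}

# Covariate class probabilities; Missing is injected separately.
covariate_levels <- function() {
  list(
    race = list(levels = c("Brown", "Caucasian", "Black", "Asian", "Indigenous"),
                prob = c(0.55, 0.31, 0.11, 0.01, 0.02)),
    zone = list(levels = c("Urban", "Rural"), prob = c(0.75, 0.25)),
    water_supply = list(levels = c("Public supply", "Well", "Other"),
                        prob = c(0.66, 0.24, 0.10)),
    sewage = list(levels = c("Public collection", "Septic tank",
                             "Rudimentary pit", "Ditch", "Other"),
                  prob = c(0.40, 0.15, 0.27, 0.13, 0.05)),
    garbage = list(levels = c("Collected", "Burnt / Buried", "Landfill",
                              "Other"),
                   prob = c(0.72, 0.18, 0.08, 0.02))
  )
}

draw_covariates <- function(n, missing_rate) {
  lv <- covariate_levels()
  out <- lapply(lv, function(v) {
    x <- sample(v$levels, n, replace = TRUE, prob = v$prob)
    x[stats::runif(n) < missing_rate] <- "Missing"
    x
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

# calendar-year shift; Feb 29 falls back to Feb 28
add_years <- function(d, k) {
  y <- as.integer(format(d, "%Y")) + k
  md <- format(d, "-%m-%d")
  md[md == "-02-29"] <- "-02-28"
  as.Date(paste0(y, md))
}

random_date <- function(n, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  as.Date(sample.int(as.integer(to - from) + 1L, n, replace = TRUE) - 1L,
          origin = from)
}

random_full_name <- function(n, given, surnames) {
  vapply(seq_len(n), function(i) {
    toks <- c(sample(given, 1L),
              if (stats::runif(1) < 0.25) sample(given, 1L),
              sample(surnames, 1L + stats::rbinom(1L, 1L, 0.5)))
    paste(toks, collapse = " ")
  }, character(1))
}

#' Apply a single named corruption operator to a name
#'
#' Deterministic when `pos` (and `letter` where relevant) are supplied;
#' positions index non-space characters of the name for `substitute` and
#' `delete`, the left member of the swapped pair for `transpose`, the gap
#' (0 = before the first character) for `insert`, and the token number for
#' `drop_token`. Falls back to substitution when the requested operator
#' cannot keep the result non-empty (single-character deletion,
#' single-token drop).
#'
#' @keywords internal
apply_name_error <- function(name, op, pos = NULL, letter = NULL) {
  name <- as.character(name)
  if (!nzchar(name)) stop("cannot corrupt an empty name", call. = FALSE)
  ch <- strsplit(name, "", fixed = TRUE)[[1]]
  nonspace <- which(ch != " ")
  toks <- strsplit(name, " ", fixed = TRUE)[[1]]
  if (op == "drop_token" && length(toks) < 2L) op <- "substitute"
  if (op == "delete" && length(nonspace) < 2L) op <- "substitute"
  if (op == "transpose") {
    pairs <- nonspace[nonspace < length(ch) & ch[nonspace + 1L] != " "]
    pairs <- pairs[pairs %in% nonspace]
    if (length(pairs) == 0L) op <- "substitute"
  }
  out <- switch(op,
    substitute = {
      i <- if (is.null(pos)) sample(nonspace, 1L) else nonspace[pos]
      repl <- if (is.null(letter)) sample(setdiff(LETTERS, ch[i]), 1L) else letter
      ch[i] <- repl
      paste(ch, collapse = "")
    },
    delete = {
      i <- if (is.null(pos)) sample(nonspace, 1L) else nonspace[pos]
      paste(ch[-i], collapse = "")
    },
    insert = {
      i <- if (is.null(pos)) sample(0:length(ch), 1L) else pos
      repl <- if (is.null(letter)) sample(LETTERS, 1L) else letter
      paste(c(ch[seq_len(i)], repl, ch[seq_len(length(ch) - i) + i]),
            collapse = "")
    },
    transpose = {
      pairs <- nonspace[nonspace < length(ch) & ch[nonspace + 1L] != " "]
      i <- if (is.null(pos)) sample(pairs, 1L) else pos
      tmp <- ch[i]; ch[i] <- ch[i + 1L]; ch[i + 1L] <- tmp
      paste(ch, collapse = "")
    },
    drop_token = {
      i <- if (is.null(pos)) sample(seq_along(toks), 1L) else pos
      paste(toks[-i], collapse = " ")
    },
    stop("unknown corruption operator: ", op, call. = FALSE)
  )
  standardize_name(out)
}

#' Inject typographical errors into a standardized name
#'
#' Applies `n_errors` corruption operators, each chosen uniformly from
#' character substitution, deletion, insertion, adjacent transposition and
#' token drop, using the current random-generator state. The result is
#' always a non-empty standardized name; operators that would empty it
#' fall back to substitution.
#'
#' @param name Non-empty standardized name.
#' @param n_errors Number of errors to apply (0 returns the name unchanged).
#' @return Corrupted name.
#' @export
inject_name_errors <- function(name, n_errors = 1L) {
  if (!nzchar(name)) stop("cannot corrupt an empty name", call. = FALSE)
  ops <- c("substitute", "delete", "insert", "transpose", "drop_token")
  for (k in seq_len(n_errors)) {
    name <- apply_name_error(name, sample(ops, 1L))
  }
  name
}

#' Generate paired synthetic registers with ground truth
#'
#' Builds a cohort register of adults grouped into families, then a births
#' register in which `round(overlap_fraction * n_births)` records have a
#' true mother in the cohort. Maternal attributes on the birth side are
#' copied from the true mother and then corrupted according to the config
#' rates; the remaining births get mothers absent from the cohort. Each
#' overlapping birth's child is also planted as a cohort member of the
#' mother's family (same date of birth and sex), so offspring search can be
#' validated. Mother dates of birth are unique across cohort adults, and
#' recorded maternal age is derived from the true dates (perturbed at
#' `age_error_rate`).
#'
#' @param config A [generator_config()].
#' @param dir Optional directory; when supplied, `births.csv`, `cohort.csv`
#'   and `truth.csv` are written there.
#' @return List with data.frames `births`, `cohort` and `truth`.
#' @export
generate_population <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  given <- readLines(system.file("extdata", "given_names.txt",
                                 package = "birthlink", mustWork = TRUE))
  surnames <- readLines(system.file("extdata", "surnames.txt",
                                    package = "birthlink", mustWork = TRUE))
  geo <- synthetic_municipalities()
  y0 <- config$year_range[1]; y1 <- config$year_range[2]

  n <- config$n_cohort
  m <- config$n_births
  n_link <- round(config$overlap_fraction * m)
  fam_sizes <- sample(1:4, n, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
  fam <- rep(seq_along(fam_sizes), fam_sizes)[seq_len(n)]
  gi <- sample(nrow(geo), n, replace = TRUE)
  # distinct DOBs keep the exact-age filter's behaviour analysable; the
  # span guarantees every adult can mother a birth somewhere in year_range
  dob_pool <- seq(as.Date(sprintf("%d-01-01", y0 - 45L)),
                  as.Date(sprintf("%d-12-31", y1 - 16L)), by = "day")
  if (n > length(dob_pool)) {
    stop("`n_cohort` exceeds the distinct-DOB pool; widen `year_range`",
         call. = FALSE)
  }
  dobs <- sample(dob_pool, n, replace = FALSE)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  # every overlapping birth needs its own cohort mother
  if (n_link > n) {
    stop("`overlap_fraction` x `n_births` exceeds `n_cohort`: not enough ",
         "cohort members to mother every overlapping birth", call. = FALSE)
  }
  deficit <- n_link - sum(sex == "F")
  if (deficit > 0L) {
    males <- which(sex == "M")
    sex[if (length(males) == 1L) males else sample(males, deficit)] <- "F"
  }
  cohort <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    family_id = sprintf("F%05d", fam),
    name = random_full_name(n, given, surnames),
    dob = format(dobs, "%Y-%m-%d"),
    sex = sex,
    municipality = geo$municipality[gi],
    state = geo$state[gi],
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, draw_covariates(n, config$covariate_missing_rate))

  child_dob <- random_date(m, sprintf("%d-01-01", y0), sprintf("%d-12-31", y1))
  child_sex <- sample(c("F", "M"), m, replace = TRUE)

  women <- which(cohort$sex == "F")
  mother_rows <- rep(NA_integer_, m)
  if (n_link > 0L) {
    mother_rows[seq_len(n_link)] <-
      if (length(women) == 1L) women else sample(women, n_link)
    # child date drawn inside the overlap of year_range and the mother's
    # ages 15-45, which the DOB pool keeps non-empty
    for (b in seq_len(n_link)) {
      mdob <- as.Date(cohort$dob[mother_rows[b]])
      lo <- max(as.Date(sprintf("%d-01-01", y0)), add_years(mdob, 15L))
      hi <- min(as.Date(sprintf("%d-12-31", y1)), add_years(mdob, 46L) - 1L)
      child_dob[b] <- random_date(1L, lo, hi)
    }
  }

  mother_name <- character(m)
  mother_dob <- character(m)
  muni <- character(m); state <- character(m)
  covs <- draw_covariates(m, config$covariate_missing_rate)
  for (b in seq_len(m)) {
    if (!is.na(mother_rows[b])) {
      r <- mother_rows[b]
      mother_name[b] <- cohort$name[r]
      mother_dob[b] <- cohort$dob[r]
      muni[b] <- cohort$municipality[r]
      state[b] <- cohort$state[r]
      covs[b, ] <- cohort[r, names(covs)]
    } else {
      # mother absent from the cohort; avoid accidental full-name collisions
      nm <- random_full_name(1L, given, surnames)
      for (tries in 1:20) {
        if (!nm %in% cohort$name) break
        nm <- random_full_name(1L, given, surnames)
      }
      mother_name[b] <- nm
      mdob <- random_date(1L, format(child_dob[b] - 45 * 365.25, "%Y-%m-%d"),
                          format(child_dob[b] - 16 * 365.25, "%Y-%m-%d"))
      mother_dob[b] <- format(mdob, "%Y-%m-%d")
      g <- sample(nrow(geo), 1L)
      muni[b] <- geo$municipality[g]; state[b] <- geo$state[g]
    }
  }

  true_age <- completed_years(mother_dob, child_dob)
  rec_age <- true_age
  flip <- stats::runif(m) < config$age_error_rate
  rec_age[flip] <- rec_age[flip] + sample(c(-1L, 1L), sum(flip), replace = TRUE)

  corrupt <- stats::runif(m) < config$typo_rate
  for (b in which(corrupt)) {
    mother_name[b] <- inject_name_errors(
      mother_name[b], 1L + stats::rbinom(1L, 1L, 0.3))
  }
  mother_dob[stats::runif(m) < config$missing_mother_dob_rate] <- NA_character_

  move <- which(stats::runif(m) < config$municipality_mismatch_rate)
  if (length(move)) {
    g <- sample(nrow(geo), length(move), replace = TRUE)
    muni[move] <- geo$municipality[g]; state[move] <- geo$state[g]
  }

  births <- data.frame(
    birth_id = sprintf("B%06d", seq_len(m)),
    child_dob = format(child_dob, "%Y-%m-%d"),
    child_sex = child_sex,
    birth_year = as.integer(format(child_dob, "%Y")),
    mother_name = mother_name,
    mother_age = rec_age,
    mother_dob = mother_dob,
    municipality = muni,
    state = state,
    stringsAsFactors = FALSE
  )
  births <- cbind(births, covs)

  # plant each overlapping birth's child in the mother's family
  linked <- which(!is.na(mother_rows))
  if (length(linked)) {
    rows <- mother_rows[linked]
    kid_surname <- vapply(strsplit(cohort$name[rows], " ", fixed = TRUE),
                          function(t) t[length(t)], character(1))
    kids <- data.frame(
      person_id = sprintf("C%06d", seq_along(linked)),
      family_id = cohort$family_id[rows],
      name = paste(sample(given, length(linked), replace = TRUE), kid_surname),
      dob = births$child_dob[linked],
      sex = births$child_sex[linked],
      municipality = cohort$municipality[rows],
      state = cohort$state[rows],
      stringsAsFactors = FALSE
    )
    kids <- cbind(kids, cohort[rows, names(covariate_levels())])
    rownames(kids) <- NULL
    cohort <- rbind(cohort, kids)
  }

  truth <- data.frame(
    birth_id = births$birth_id,
    true_person_id = ifelse(is.na(mother_rows), NA_character_,
                            sprintf("P%06d", mother_rows)),
    true_family_id = ifelse(is.na(mother_rows), NA_character_,
                            sprintf("F%05d", fam[mother_rows])),
    stringsAsFactors = FALSE
  )

  out <- list(births = births, cohort = cohort, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nmf in names(out)) {
      utils::write.csv(out[[nmf]], file.path(dir, paste0(nmf, ".csv")),
                       row.names = FALSE, na = "")
    }
  }
  out
}
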