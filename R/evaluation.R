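#' Round half away from zero
#'
#' Presentation rounding for report percentages (half-up at the given
#' number of decimals), as opposed to base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Yearly linkage-rate table from submitted/linked counts
#'
#' The arithmetic behind the yearly report: per-year linked percentage
#' (100 x linked / submitted, rounded half-up to 2 decimals) plus a Total
#' row summing the years.
#'
#' @param counts data.frame with columns `year`, `submitted`, `linked`.
#' @return data.frame `year`, `submitted`, `linked`, `pct_linked` with a
#'   final `"Total"` row.
#' @export
linkage_rate_table <- function(counts) {
  stopifnot(all(c("year", "submitted", "linked") %in% names(counts)))
  out <- counts[order(counts$year), c("year", "submitted", "linked")]
  out$year <- as.character(out$year)
  out <- rbind(out, data.frame(year = "Total",
                               submitted = sum(out$submitted),
                               linked = sum(out$linked)))
  out$pct_linked <- round_half_up(100 * out$linked / out$submitted, 2L)
  rownames(out) <- NULL
  out
}

#' Yearly linkage-rate table from classified decisions
#'
#' Counts submitted and linked births per birth year and renders the
#' percentage table via [linkage_rate_table()].
#'
#' @param decisions Classified assignments from [classify_links()].
#' @param births Births register carrying `birth_id` and `birth_year`.
#' @return data.frame as in [linkage_rate_table()].
#' @export
linkage_rate_by_year <- function(decisions, births) {
  year <- births$birth_year[match(decisions$birth_id, births$birth_id)]
  if (anyNA(year)) {
    stop("missing birth year for: ",
         decisions$birth_id[which(is.na(year))[1]], call. = FALSE)
  }
  linked <- decisions$classification == "link"
  counts <- data.frame(
    year = sort(unique(year)),
    submitted = as.integer(table(year)),
    linked = as.integer(table(factor(year[linked],
                                     levels = sort(unique(year)))))
  )
  linkage_rate_table(counts)
}

#' Truth-based linkage accuracy metrics
#'
#' Pair-level confusion-matrix arithmetic against the ground-truth table:
#' a link is a true positive iff its cohort id equals the true mother id;
#' links to the wrong record or for births with no true mother are false
#' positives; births with a true mother that end up unlinked or
#' wrongly linked are missed matches. Sensitivity and the missed-match
#' rate are complements by construction.
#'
#' @param decisions Classified assignments from [classify_links()].
#' @param truth Truth table (`birth_id`, `true_person_id`).
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `missed_match_rate` (1 - sensitivity), `false_match_rate`
#'   (false links / all links), and the underlying counts.
#' @export
truth_metrics <- function(decisions, truth) {
  j <- match(decisions$birth_id, truth$birth_id)
  if (anyNA(j)) {
    stop("birth absent from truth table: ",
         decisions$birth_id[which(is.na(j))[1]], call. = FALSE)
  }
  true_id <- truth$true_person_id[j]
  is_link <- decisions$classification == "link"
  has_truth <- !is.na(true_id)
  correct <- is_link & has_truth & decisions$cohort_id == true_id

  tp <- sum(correct)
  fp <- sum(is_link & !correct)
  fn <- sum(has_truth) - tp
  tn <- sum(!has_truth & !is_link)

  list(
    sensitivity = tp / sum(has_truth),
    specificity = if (sum(!has_truth) > 0) tn / sum(!has_truth) else NA_real_,
    ppv = if (sum(is_link) > 0) tp / sum(is_link) else NA_real_,
    npv = if (sum(!is_link) > 0) sum(!has_truth & !is_link) / sum(!is_link)
          else NA_real_,
    missed_match_rate = 1 - tp / sum(has_truth),
    false_match_rate = if (sum(is_link) > 0) fp / sum(is_link) else 0,
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)
  )
}

#' Linked vs non-linked covariate comparison
#'
#' For each requested covariate, tabulates counts and column percentages
#' of every category — including an explicit `Missing` row, never dropped —
#' among linked and among non-linked births, the descriptive contrast used
#' to look for linkage bias. Optionally restricted to selected birth
#' years.
#'
#' @param decisions Classified assignments from [classify_links()].
#' @param births Births register carrying the covariate columns.
#' @param covariates Character vector of covariate column names (default:
#'   the generator's five socio-demographic covariates).
#' @param years Optional integer vector of birth years to keep.
#' @return data.frame `covariate`, `category`, `n_linked`, `pct_linked`,
#'   `n_non_linked`, `pct_non_linked`; within each covariate and group the
#'   percentages sum to 100 up to rounding.
#' @export
compare_characteristics <- function(decisions, births,
                                    covariates = names(covariate_levels()),
                                    years = NULL) {
  missing_cov <- setdiff(covariates, names(births))
  if (length(missing_cov)) {
    stop("unknown covariate(s): ", paste(missing_cov, collapse = ", "),
         "; available: ", paste(names(births), collapse = ", "),
         call. = FALSE)
  }
  bi <- match(decisions$birth_id, births$birth_id)
  keep <- rep(TRUE, nrow(decisions))
  if (!is.null(years)) keep <- births$birth_year[bi] %in% years
  linked <- decisions$classification[keep] == "link"
  rows <- bi[keep]
  out <- lapply(covariates, function(cv) {
    x <- births[[cv]][rows]
    x[is.na(x)] <- "Missing"
    lv <- unique(c(setdiff(sort(unique(x)), "Missing"),
                   if ("Missing" %in% x) "Missing"))
    nl <- table(factor(x[linked], levels = lv))
    nn <- table(factor(x[!linked], levels = lv))
    data.frame(
      covariate = cv, category = lv,
      n_linked = as.integer(nl),
      pct_linked = round_half_up(100 * as.integer(nl) / max(sum(nl), 1L), 2L),
      n_non_linked = as.integer(nn),
      pct_non_linked = round_half_up(100 * as.integer(nn) / max(sum(nn), 1L),
                                     2L),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired ablation of the mother date-of-birth attribute
#'
#' Runs the full pipeline twice on identical inputs — once using the
#' mother's date of birth whenever present (`dob` route) and once ignoring
#' it entirely (`age` route, the exact-age consistency regime) — and
#' reports AUC, chosen threshold, sensitivity/specificity at the
#' threshold, and truth-based accuracy for each route side by side.
#'
#' @param births,cohort,truth A register triple from
#'   [generate_population()].
#' @param weights,k,dl_floor Linkage parameters.
#' @param sample_size,seed Stratified-sample parameters for threshold
#'   selection.
#' @return data.frame with one metric column per route (`dob`, `age`).
#' @export
ablation_report <- function(births, cohort, truth,
                            weights = default_weights(), k = 1000L,
                            dl_floor = 0.5, sample_size = 2000L, seed = 1L) {
  idx <- build_index(cohort)
  one_route <- function(era) {
    res <- link_records(births, idx, weights = weights, k = k,
                        dl_floor = dl_floor, era = era)
    samp <- stratify_sample(res$assignments, sample_size = sample_size,
                            seed = seed)
    model <- select_link_threshold(attach_labels(samp, truth = truth))
    dec <- classify_links(res$assignments, model$threshold)
    tm <- truth_metrics(dec, truth)
    c(auc = model$auc, threshold = model$threshold,
      roc_sensitivity = model$sensitivity, roc_specificity = model$specificity,
      sensitivity = tm$sensitivity, false_match_rate = tm$false_match_rate)
  }
  dob <- one_route("dob")
  age <- one_route("age")
  data.frame(metric = names(dob), dob = unname(dob), age = unname(age),
             stringsAsFactors = FALSE)
}
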