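#' Stratified sample of assigned pairs for labeling
#'
#' Draws a sample of assigned (birth, cohort) pairs stratified by linkage
#' score: low (below the first bound), intermediate (the closed interval
#' between the bounds) and high (above the second bound). Allocation is
#' proportional to stratum size with a floor of `min_per_stratum` in every
#' non-empty stratum; sampling is without replacement and deterministic
#' under the seed.
#'
#' @param assignments Assignments from [link_records()]; unmatched births
#'   are ignored.
#' @param sample_size Total pairs to sample (default 2000).
#' @param bounds Two score bounds defining the strata (default
#'   `c(0.90, 0.95)`).
#' @param min_per_stratum Floor per non-empty stratum (default 10).
#' @param seed Integer seed for the draw.
#' @return data.frame of sampled pairs with a `stratum` column.
#' @export
stratify_sample <- function(assignments, sample_size = 2000L,
                            bounds = c(0.90, 0.95), min_per_stratum = 10L,
                            seed = 1L) {
  pool <- assignments[!is.na(assignments$cohort_id), , drop = FALSE]
  if (nrow(pool) == 0L) stop("no assigned pairs to sample", call. = FALSE)
  stratum <- ifelse(pool$score < bounds[1], "low",
                    ifelse(pool$score <= bounds[2], "intermediate", "high"))
  pool$stratum <- factor(stratum, levels = c("low", "intermediate", "high"))
  sizes <- table(pool$stratum)
  nonempty <- names(sizes)[sizes > 0L]
  if (sample_size < length(nonempty) * min_per_stratum) {
    stop("`sample_size` below the per-stratum minimum (",
         length(nonempty), " strata x ", min_per_stratum, ")", call. = FALSE)
  }
  total <- sum(sizes)
  want <- pmin(as.integer(sizes),
               pmax(round(sample_size * as.integer(sizes) / total),
                    ifelse(as.integer(sizes) > 0L, min_per_stratum, 0L)))
  names(want) <- names(sizes)
  # trim any rounding overshoot, never below the per-stratum floor
  while (sum(want) > sample_size) {
    eligible <- which(want > min_per_stratum)
    if (!length(eligible)) eligible <- which(want > 0L)
    j <- eligible[which.max(want[eligible])]
    want[j] <- want[j] - 1L
  }
  set.seed(seed)
  picks <- lapply(names(sizes), function(s) {
    rows <- which(pool$stratum == s)
    if (length(rows) <= want[[s]]) rows else sort(sample(rows, want[[s]]))
  })
  out <- pool[unlist(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label a sampled set of pairs
#'
#' Stands in for clerical review. With a truth table, a pair is labeled
#' `TRUE` iff its assigned cohort id equals the true mother id. With a
#' review file (data.frame `birth_id`, `label` of `"true"`/`"false"`),
#' labels come from the file and every sampled pair must be covered.
#'
#' @param sample Output of [stratify_sample()].
#' @param truth Optional truth table (`birth_id`, `true_person_id`).
#' @param review Optional review data.frame (`birth_id`, `label`).
#' @return `sample` with a logical `label` column.
#' @export
attach_labels <- function(sample, truth = NULL, review = NULL) {
  if (!is.null(truth)) {
    j <- match(sample$birth_id, truth$birth_id)
    if (anyNA(j)) {
      stop("birth absent from truth table: ",
           sample$birth_id[which(is.na(j))[1]], call. = FALSE)
    }
    sample$label <- !is.na(truth$true_person_id[j]) &
      sample$cohort_id == truth$true_person_id[j]
  } else if (!is.null(review)) {
    j <- match(sample$birth_id, review$birth_id)
    if (anyNA(j)) {
      stop("unlabeled sampled pair: ", sample$birth_id[which(is.na(j))[1]],
           call. = FALSE)
    }
    sample$label <- review$label[j] %in% c("true", TRUE)
  } else {
    stop("supply either `truth` or `review`", call. = FALSE)
  }
  sample
}

#' Build a ROC curve over a labeled sample
#'
#' Classification rule: score >= cut-off is a link. Cut points are every
#' distinct observed score (plus a cut above the maximum, giving the
#' (0, 0) corner); sensitivity and specificity follow from direct
#' confusion-matrix arithmetic at each cut, and the AUC is the trapezoidal
#' integral of TPR over FPR. Both label classes must be present.
#'
#' @param labeled Output of [attach_labels()].
#' @return A `threshold_model` list: `roc` (data.frame `threshold`, `tpr`,
#'   `fpr`, `sensitivity`, `specificity`), `auc`, and `threshold` (unset,
#'   `NA`, until [choose_threshold()]).
#' @export
build_roc <- function(labeled) {
  lab <- labeled$label
  if (length(unique(lab)) < 2L) {
    stop("both label classes are required to build a ROC curve",
         call. = FALSE)
  }
  sc <- labeled$score
  cuts <- sort(unique(sc), decreasing = TRUE)
  cuts <- c(max(sc) + 1, cuts)  # empty-link corner first
  P <- sum(lab); N <- sum(!lab)
  tpr <- vapply(cuts, function(t) sum(sc >= t & lab) / P, numeric(1))
  fpr <- vapply(cuts, function(t) sum(sc >= t & !lab) / N, numeric(1))
  roc <- data.frame(threshold = cuts, tpr = tpr, fpr = fpr,
                    sensitivity = tpr, specificity = 1 - fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = roc, auc = auc, threshold = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 degenerate = FALSE, n = nrow(labeled)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("threshold_model: AUC", format(x$auc, digits = 4))
  if (!is.na(x$threshold)) {
    cat("; threshold", format(x$threshold, digits = 4),
        sprintf("(sens %.3f, spec %.3f)", x$sensitivity, x$specificity))
  }
  cat("\n")
  invisible(x)
}

#' Choose the operating threshold on a ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the ROC cut
#' points, breaking ties toward the higher threshold (favoring
#' specificity).
#'
#' @param model A [build_roc()] result.
#' @return The model with `threshold`, `sensitivity` and `specificity`
#'   filled in.
#' @export
choose_threshold <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  j <- model$roc$sensitivity + model$roc$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.max(model$roc$threshold[best])]
  model$threshold <- min(model$roc$threshold[pick], 1)
  model$sensitivity <- model$roc$sensitivity[pick]
  model$specificity <- model$roc$specificity[pick]
  model
}

#' Select the link threshold from a labeled sample
#'
#' Builds the ROC and chooses the Youden-optimal cut. The degenerate
#' all-true sample (possible on noise-free data, where every assigned pair
#' is correct) cannot support a ROC curve; it yields the minimum observed
#' score as the threshold, flagged as degenerate, with AUC undefined.
#'
#' @param labeled Output of [attach_labels()].
#' @return A `threshold_model` with the threshold chosen.
#' @export
select_link_threshold <- function(labeled) {
  if (all(labeled$label)) {
    return(structure(list(roc = NULL, auc = NA_real_,
                          threshold = min(labeled$score),
                          sensitivity = 1, specificity = NA_real_,
                          degenerate = TRUE, n = nrow(labeled)),
                     class = "threshold_model"))
  }
  choose_threshold(build_roc(labeled))
}

#' Classify assignments under a single threshold
#'
#' Score at or above the threshold is a link; anything else (including
#' births with no assigned candidate) is a non-link. The threshold is
#' clamped to `[0, 1]`.
#'
#' @param assignments Assignments from [link_records()].
#' @param threshold Scalar threshold.
#' @return `assignments` with a `classification` column
#'   (`"link"`/`"non_link"`); non-links keep their candidate id and score
#'   for audit but are not linked.
#' @export
classify_links <- function(assignments, threshold) {
  threshold <- min(max(threshold, 0), 1)
  link <- !is.na(assignments$cohort_id) & assignments$score >= threshold
  assignments$classification <- ifelse(link, "link", "non_link")
  assignments
}
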