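#' 2x2 confusion counts
#'
#' Algorithm label (case / not case) against a gold-standard label.
#'
#' @param tp,fp,fn,tn non-negative integer counts: true positives, false
#'   positives, false negatives, true negatives.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3], tn = counts[4]),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts>\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(gold = c("case", "not_case"),
                              algorithm = c("case", "not_case")))
  print(m)
  invisible(x)
}

#' Diagnostic-test metrics from a 2x2 table
#'
#' Exact proportions: PPV = tp/(tp+fp), NPV = tn/(fn+tn), sensitivity =
#' tp/(tp+fn), specificity = tn/(fp+tn). A metric whose denominator is zero
#' is returned as NA (an explicit missing marker). Use [pct_int()] for the
#' integer-percent rendering used in published 2x2 tables (round half away
#' from zero).
#'
#' @param counts a [confusion_counts()].
#' @return object of class `test_metrics`: list with exact `ppv`, `npv`,
#'   `sensitivity`, `specificity`, the counts, and `percent`, the
#'   integer-percent rendering of each metric.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  metrics <- list(
    ppv = ratio(counts$tp, counts$tp + counts$fp),
    npv = ratio(counts$tn, counts$fn + counts$tn),
    sensitivity = ratio(counts$tp, counts$tp + counts$fn),
    specificity = ratio(counts$tn, counts$fp + counts$tn)
  )
  structure(c(metrics, list(counts = counts,
                            percent = lapply(metrics, pct_int))),
            class = "test_metrics")
}

#' @export
print.test_metrics <- function(x, ...) {
  cat("<test_metrics>\n")
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %-12s %s%%\n", nm,
                ifelse(is.na(x$percent[[nm]]), "NA", x$percent[[nm]])))
  }
  invisible(x)
}

#' Positive predictive value from a chart review
#'
#' The proportion of reviewer-confirmed true positives out of the reviewed
#' algorithm-identified cases.
#'
#' @param n_true_positive reviewer-confirmed cases among those reviewed.
#' @param n_reviewed number of charts reviewed (> 0).
#' @return list with exact `ppv` and integer `percent`.
#' @export
ppv_from_review <- function(n_true_positive, n_reviewed) {
  if (n_reviewed <= 0) stop("n_reviewed must be positive", call. = FALSE)
  if (n_true_positive < 0 || n_true_positive > n_reviewed) {
    stop("n_true_positive must lie in [0, n_reviewed]", call. = FALSE)
  }
  p <- n_true_positive / n_reviewed
  list(ppv = p, percent = pct_int(p))
}

#' EHR prevalence of an algorithm-defined phenotype
#'
#' Cases identified by an algorithm out of the eligible population, as a
#' percentage rendered to 2 significant figures (the convention used for
#' published EHR prevalence cells, e.g. 5.8, 0.88, 0.65).
#'
#' @param n_cases case count.
#' @param n_population eligible population size (> 0).
#' @return list with `n_cases`, `n_population`, exact `prevalence_pct`, and
#'   `rendered` (2 significant figures).
#' @export
prevalence <- function(n_cases, n_population) {
  if (n_population <= 0) stop("n_population must be positive", call. = FALSE)
  if (n_cases < 0 || n_cases > n_population) {
    stop("n_cases must lie in [0, n_population]", call. = FALSE)
  }
  pct <- 100 * n_cases / n_population
  list(n_cases = n_cases, n_population = n_population,
       prevalence_pct = pct, rendered = signif(pct, 2))
}

#' Build a 2x2 against a gold standard
#'
#' Crosses an algorithm's case/not-case labels with gold labels over an
#' evaluation frame. In the published design the frame is the medical-home
#' population intersected with the data floor (at least one ICD10 E28.2
#' code); pass the frame's patient ids via `frame_ids`, or all shared ids
#' are used.
#'
#' @param assignments a `cohort_assignment` from [build_cohorts()].
#' @param truth data frame with `patient_id` and logical `true_case` (the
#'   simulated chart-review gold standard or stored reviewer labels).
#' @param algorithm name of the algorithm column to evaluate.
#' @param frame_ids optional patient ids defining the evaluation frame.
#' @return a [confusion_counts()].
#' @export
evaluate_against_truth <- function(assignments, truth, algorithm,
                                   frame_ids = NULL) {
  if (!algorithm %in% names(assignments)) {
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  }
  df <- dplyr::inner_join(
    assignments[, c("patient_id", algorithm)],
    truth[, c("patient_id", "true_case")],
    by = "patient_id"
  )
  missing <- setdiff(assignments$patient_id, truth$patient_id)
  if (!is.null(frame_ids)) {
    missing <- intersect(missing, frame_ids)
    df <- df[df$patient_id %in% frame_ids, ]
  }
  if (length(missing)) {
    stop("patient ids missing from truth: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  }
  alg <- df[[algorithm]]
  keep <- !is.na(alg)
  alg <- alg[keep]
  gold <- df$true_case[keep]
  confusion_counts(
    tp = sum(alg & gold), fp = sum(alg & !gold),
    fn = sum(!alg & gold), tn = sum(!alg & !gold)
  )
}

#' Wilson score interval for a proportion
#'
#' Available for uncertainty reporting around PPV/sensitivity estimates;
#' not part of the published table layouts.
#'
#' @param successes,n counts.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
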