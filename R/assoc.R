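#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon test. With a combined sample size of at
#' most 20 and no ties the exact null distribution is used; otherwise the
#' normal approximation with tie correction and continuity correction.
#' Group medians and quartiles are reported alongside the test, matching
#' how published group comparisons pair the P value with median (IQR)
#' summaries.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return object of class `rank_sum_result`: list with `n_x`, `n_y`,
#'   `statistic` (Mann-Whitney U for `x`), `p_value`, `exact`, and
#'   `summary_x`/`summary_y` (median, q25, q75).
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)
  )
  qs <- function(v) c(median = stats::median(v),
                      q25 = stats::quantile(v, 0.25, type = 7, names = FALSE),
                      q75 = stats::quantile(v, 0.75, type = 7, names = FALSE))
  structure(list(
    n_x = length(x), n_y = length(y),
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    exact = use_exact,
    summary_x = qs(x), summary_y = qs(y)
  ), class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat("<rank_sum_result> U =", x$statistic, " p =", format.pval(x$p_value),
      if (x$exact) "(exact)" else "(normal approx., tie/continuity corrected)",
      "\n")
  invisible(x)
}

#' Match controls to cases on age and race
#'
#' Cases and candidate controls are binned into cells of (age bin x
#' stratum); within each occupied cell controls are sampled without
#' replacement at `ratio` controls per case. When a cell has too few
#' controls the achieved ratio degrades with a warning; a cell with no
#' controls at all drops its cases from the matched set with a warning.
#'
#' @param cohort data frame with `patient_id`, `case` (logical), `age`,
#'   `stratum`.
#' @param ratio controls per case (default 4).
#' @param age_bin_width age bin width in years (default 5).
#' @param seed integer seed for reproducible sampling.
#' @return tibble of matched patients: `patient_id`, `case`, `age`,
#'   `stratum`, `cell`.
#' @export
match_cases_controls <- function(cohort, ratio = 4, age_bin_width = 5,
                                 seed = 1L) {
  cohort <- tibble::as_tibble(cohort)
  check_columns(cohort, c("patient_id", "case", "age", "stratum"), "cohort")
  cohort <- cohort[!is.na(cohort$age) & !is.na(cohort$case), ]
  lo <- floor(min(cohort$age) / age_bin_width) * age_bin_width
  hi <- ceiling((max(cohort$age) + 1e-9) / age_bin_width) * age_bin_width
  cohort$cell <- paste(
    cut(cohort$age, seq(lo, hi, by = age_bin_width), right = FALSE,
        include.lowest = TRUE),
    cohort$stratum, sep = " / ")

  pieces <- list()
  with_stream(seed, "matching", {
    for (cell in sort(unique(cohort$cell[cohort$case]))) {
      cases <- cohort[cohort$case & cohort$cell == cell, ]
      ctrls <- cohort[!cohort$case & cohort$cell == cell, ]
      if (!nrow(ctrls)) {
        warning("no controls available in cell '", cell, "'; its ",
                nrow(cases), " case(s) dropped from the matched set",
                call. = FALSE)
        next
      }
      want <- ratio * nrow(cases)
      if (nrow(ctrls) < want) {
        warning("cell '", cell, "': only ", nrow(ctrls), " controls for ",
                nrow(cases), " cases (wanted ", want, ")", call. = FALSE)
        take <- ctrls
      } else {
        take <- ctrls[sample.int(nrow(ctrls), want), ]
      }
      pieces[[cell]] <- dplyr::bind_rows(cases, take)
    }
  })
  dplyr::bind_rows(pieces)
}

#' Nagelkerke pseudo-R-squared
#'
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]` for a fitted binomial GLM versus
#' its intercept-only null.
#'
#' @param fit a binomial `glm`.
#' @return pseudo-R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  n <- stats::nobs(fit)
  ll1 <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(fit$y ~ 1, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(null_fit))
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  max_r2 <- 1 - exp((2 / n) * ll0)
  max(0, cox_snell / max_r2)
}

#' Logistic PRS-association model
#'
#' Fits case status on the polygenic risk score with covariates by
#' maximum-likelihood logistic regression (IRLS, relative convergence
#' tolerance 1e-8). The PRS is standardised to unit standard deviation
#' within the analysis sample by default, so the reported odds ratio is
#' per SD of the score; a zero-variance PRS is left unstandardised and
#' yields a null fit (pseudo-R-squared 0). Wald 95% confidence intervals.
#'
#' @param data data frame with logical/0-1 `case`, numeric `prs`, and any
#'   covariate columns.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("median_age", paste0("pc", 1:10))`).
#' @param standardize_prs scale PRS to unit SD within the sample?
#' @param min_cases,min_controls minimum group sizes (default 10 each).
#' @param label optional algorithm/stratum label carried into the result.
#' @return object of class `prs_assoc_result`: `n_cases`, `n_controls`,
#'   `beta` (log-odds per SD), `se`, `p`, `or`, `ci95`, `pseudo_r2`.
#' @export
logistic_prs_assoc <- function(data, covariates = character(),
                               standardize_prs = TRUE,
                               min_cases = 10, min_controls = 10,
                               label = NULL) {
  data <- tibble::as_tibble(data)
  check_columns(data, c("case", "prs", covariates), "data")
  data <- data[stats::complete.cases(data[, c("case", "prs", covariates)]), ]
  data$case <- as.integer(data$case)
  n_cases <- sum(data$case == 1)
  n_controls <- sum(data$case == 0)
  if (n_cases < min_cases || n_controls < min_controls) {
    stop("need at least ", min_cases, " cases and ", min_controls,
         " controls; got ", n_cases, "/", n_controls, call. = FALSE)
  }
  prs_sd <- stats::sd(data$prs)
  data$prs_std <- if (standardize_prs && prs_sd > 0) {
    (data$prs - mean(data$prs)) / prs_sd
  } else {
    data$prs
  }
  rhs <- paste(c("prs_std", covariates), collapse = " + ")
  fit <- stats::glm(stats::as.formula(paste("case ~", rhs)), data = data,
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    stop("logistic model failed to converge within 100 IRLS iterations",
         call. = FALSE)
  }
  co <- summary(fit)$coefficients
  if (!"prs_std" %in% rownames(co)) {
    # aliased (zero-variance) PRS: null association by construction
    return(structure(list(label = label, n_cases = n_cases,
                          n_controls = n_controls, beta = NA_real_,
                          se = NA_real_, p = NA_real_, or = NA_real_,
                          ci95 = c(NA_real_, NA_real_), pseudo_r2 = 0),
                     class = "prs_assoc_result"))
  }
  beta <- co["prs_std", "Estimate"]
  se <- co["prs_std", "Std. Error"]
  if (!is.finite(se) || se > 50) {
    stop("(quasi-)separation detected: PRS coefficient has unbounded ",
         "standard error", call. = FALSE)
  }
  structure(list(
    label = label, n_cases = n_cases, n_controls = n_controls,
    beta = beta, se = se, p = co["prs_std", "Pr(>|z|)"],
    or = exp(beta),
    ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    pseudo_r2 = nagelkerke_r2(fit)
  ), class = "prs_assoc_result")
}

#' @export
print.prs_assoc_result <- function(x, ...) {
  cat("<prs_assoc_result>", if (!is.null(x$label)) x$label, "\n")
  cat(sprintf("  cases/controls: %d/%d\n", x$n_cases, x$n_controls))
  cat(sprintf("  OR per SD: %.3f (95%% CI %.3f-%.3f), p = %s\n",
              x$or, x$ci95[1], x$ci95[2], format.pval(x$p)))
  cat(sprintf("  Nagelkerke pseudo-R2: %.4f\n", x$pseudo_r2))
  invisible(x)
}

#' Linear PRS-association model for quantitative traits
#'
#' Ordinary least squares of an (age-adjusted, inverse-normal-transformed)
#' lab value on the PRS plus covariates. The PRS partial R-squared is the
#' difference between the full model's R-squared and the covariates-only
#' model's.
#'
#' @param data data frame with numeric `z` (outcome), `prs`, covariates.
#' @param covariates covariate column names.
#' @param standardize_prs scale PRS to unit SD within the sample?
#' @param min_n minimum complete observations (default 30).
#' @return list with `n`, `beta`, `se`, `p`, `r2_prs`.
#' @export
linear_prs_assoc <- function(data, covariates = character(),
                             standardize_prs = TRUE, min_n = 30) {
  data <- tibble::as_tibble(data)
  check_columns(data, c("z", "prs", covariates), "data")
  data <- data[stats::complete.cases(data[, c("z", "prs", covariates)]), ]
  if (nrow(data) < min_n) {
    stop("need at least ", min_n, " complete observations; got ", nrow(data),
         call. = FALSE)
  }
  prs_sd <- stats::sd(data$prs)
  data$prs_std <- if (standardize_prs && prs_sd > 0) {
    (data$prs - mean(data$prs)) / prs_sd
  } else {
    data$prs
  }
  rhs_full <- paste(c("prs_std", covariates), collapse = " + ")
  full <- stats::lm(stats::as.formula(paste("z ~", rhs_full)), data = data)
  if (any(is.na(stats::coef(full)))) {
    stop("rank-deficient design matrix (aliased covariates)", call. = FALSE)
  }
  base <- if (length(covariates)) {
    stats::lm(stats::as.formula(paste("z ~", paste(covariates, collapse = " + "))),
              data = data)
  } else {
    stats::lm(z ~ 1, data = data)
  }
  co <- summary(full)$coefficients
  list(
    n = nrow(data),
    beta = co["prs_std", "Estimate"],
    se = co["prs_std", "Std. Error"],
    p = co["prs_std", "Pr(>|t|)"],
    r2_prs = summary(full)$r.squared - summary(base)$r.squared
  )
}

#' Multiple-testing correction thresholds
#'
#' Bonferroni thresholds `alpha / m` for a set of independent tests and for
#' the full (possibly nested/overlapping) test count, plus a
#' Benjamini-Hochberg step-up helper for false-discovery-rate control.
#'
#' @param m_independent number of independent tests.
#' @param m_all total number of tests performed.
#' @param alpha family-wise error rate (default 0.05).
#' @return object of class `correction_thresholds`: `alpha`,
#'   `m_independent`, `m_all`, `threshold_independent`, `threshold_all`,
#'   `fdr_q`.
#' @export
correction_thresholds <- function(m_independent, m_all = m_independent,
                                  alpha = 0.05) {
  if (m_independent < 1 || m_all < 1) stop("m must be >= 1", call. = FALSE)
  structure(list(
    alpha = alpha,
    m_independent = as.integer(m_independent),
    m_all = as.integer(m_all),
    threshold_independent = alpha / m_independent,
    threshold_all = alpha / m_all,
    fdr_q = 0.05
  ), class = "correction_thresholds")
}

#' @export
print.correction_thresholds <- function(x, ...) {
  cat("<correction_thresholds> alpha =", x$alpha, "\n")
  cat(sprintf("  independent (m = %d): P < %.3g\n", x$m_independent,
              x$threshold_independent))
  cat(sprintf("  all tests   (m = %d): P < %.3g\n", x$m_all, x$threshold_all))
  invisible(x)
}

#' Benjamini-Hochberg rejections
#'
#' @param p vector of p-values.
#' @param q target false discovery rate (default 0.05).
#' @return logical vector: which hypotheses are rejected at FDR `q`.
#' @export
bh_reject <- function(p, q = 0.05) {
  stats::p.adjust(p, method = "BH") <= q
}
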