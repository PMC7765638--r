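#' Clean a raw laboratory table
#'
#' QualityLab-style cleaning chain, applied in a fixed order:
#' 1. drop rows whose raw value is non-numeric;
#' 2. drop analytes observed in only one patient;
#' 3. drop exact duplicate (patient, analyte, date, value, unit) rows;
#' 4. within each analyte keep only the modal unit (ties broken
#'    alphabetically for determinism), dropping discordant-unit rows;
#' 5. collapse to one row per (patient, analyte): the median value across
#'    that patient's measurements.
#'
#' Every drop reason is counted in the `drop_log` attribute. When a patient
#' table is supplied, the median age at measurement is carried along (the
#' "age at the laboratory" used for age adjustment; for patients with
#' multiple measurements this is the median age across them, consistent
#' with median-value aggregation).
#'
#' @param labs data frame with `patient_id`, `analyte`, `value` (character
#'   or numeric), `unit`, `date`.
#' @param patients optional patient table with `patient_id`, `birth_date`.
#' @return tibble with one row per (patient, analyte): `patient_id`,
#'   `analyte`, `median_value`, `unit`, `n_raw` and, when ages are
#'   available, `median_age`. Attribute `drop_log` counts dropped rows per
#'   step.
#' @export
clean_lab_table <- function(labs, patients = NULL) {
  labs <- tibble::as_tibble(labs)
  check_columns(labs, c("patient_id", "analyte", "value", "unit", "date"), "labs")
  log <- c(nonnumeric = 0L, single_patient_analyte = 0L, duplicate = 0L,
           discordant_unit = 0L)

  labs$parsed <- suppressWarnings(as.numeric(labs$value))
  bad <- is.na(labs$parsed)
  log["nonnumeric"] <- sum(bad)
  labs <- labs[!bad, ]

  if (nrow(labs)) {
    pat_per_analyte <- tapply(labs$patient_id, labs$analyte,
                              function(x) length(unique(x)))
    singletons <- names(pat_per_analyte)[pat_per_analyte < 2]
    bad <- labs$analyte %in% singletons
    log["single_patient_analyte"] <- sum(bad)
    labs <- labs[!bad, ]
  }

  if (nrow(labs)) {
    key <- labs[, c("patient_id", "analyte", "date", "parsed", "unit")]
    dup <- duplicated(key)
    log["duplicate"] <- sum(dup)
    labs <- labs[!dup, ]
  }

  if (nrow(labs)) {
    modal_unit <- labs |>
      dplyr::count(.data$analyte, .data$unit) |>
      dplyr::arrange(.data$analyte, dplyr::desc(.data$n), .data$unit) |>
      dplyr::distinct(.data$analyte, .keep_all = TRUE) |>
      dplyr::select("analyte", modal = "unit")
    labs <- dplyr::left_join(labs, modal_unit, by = "analyte")
    bad <- labs$unit != labs$modal
    log["discordant_unit"] <- sum(bad)
    labs <- labs[!bad, ]
    labs$modal <- NULL
  }

  if (!is.null(patients)) {
    labs <- dplyr::left_join(labs, patients[, c("patient_id", "birth_date")],
                             by = "patient_id")
    labs$age <- as.numeric(labs$date - labs$birth_date) / DAYS_PER_YEAR
  } else {
    labs$age <- NA_real_
  }

  out <- labs |>
    dplyr::group_by(.data$patient_id, .data$analyte) |>
    dplyr::summarise(
      median_value = stats::median(.data$parsed),
      unit = .data$unit[1],
      n_raw = dplyr::n(),
      median_age = stats::median(.data$age),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id, .data$analyte)
  if (is.null(patients)) out$median_age <- NULL
  attr(out, "drop_log") <- log
  out
}

#' Trim extreme percentile outliers
#'
#' Removes values strictly below the 1st percentile or strictly above the
#' 99th percentile of the per-patient-median distribution of each analyte.
#' Percentiles use linear interpolation (R quantile type 7). Applied to the
#' per-patient medians — the unit entering analysis — not raw repeats;
#' distributions with fewer than `min_n` values are left untrimmed with a
#' warning.
#'
#' @param series tibble from [clean_lab_table()] (or any frame with
#'   `analyte` and `median_value`).
#' @param lower,upper trimming probabilities (defaults 0.01 and 0.99).
#' @param min_n minimum number of values required before trimming.
#' @return the trimmed tibble; attribute `n_trimmed` counts removed rows
#'   per analyte.
#' @export
trim_percentile_outliers <- function(series, lower = 0.01, upper = 0.99,
                                     min_n = 10) {
  series <- tibble::as_tibble(series)
  check_columns(series, c("analyte", "median_value"), "series")
  trimmed <- integer(0)
  keep <- rep(TRUE, nrow(series))
  for (an in unique(series$analyte)) {
    idx <- which(series$analyte == an)
    v <- series$median_value[idx]
    if (length(v) < min_n) {
      warning("analyte '", an, "' has fewer than ", min_n,
              " values; not trimmed", call. = FALSE)
      trimmed[an] <- 0L
      next
    }
    q <- stats::quantile(v, c(lower, upper), type = 7, names = FALSE)
    out <- v < q[1] | v > q[2]
    keep[idx[out]] <- FALSE
    trimmed[an] <- sum(out)
  }
  res <- series[keep, ]
  attr(res, "n_trimmed") <- trimmed
  res
}

#' Age-adjusted rank-based inverse normal transformation
#'
#' Regresses each analyte's per-patient median on age at measurement by
#' ordinary least squares and maps the residuals through a rank-based
#' inverse normal transformation with Blom offsets:
#' `z = qnorm((rank - 3/8) / (n + 1/4))`, ties receiving average ranks. The
#' result is an age-adjusted, approximately standard-normal value per
#' patient, suitable as the outcome of downstream genetic association
#' models. With zero age variance the regression is skipped (with a
#' warning) and raw values are transformed.
#'
#' @param series tibble with `patient_id`, `analyte`, `median_value` and
#'   `median_age` (as produced by [clean_lab_table()] with a patient
#'   table).
#' @param min_n minimum complete observations per analyte (default 20);
#'   analytes below it are dropped with a warning.
#' @return tibble with `patient_id`, `analyte`, `z`.
#' @export
age_adjust_inverse_normal <- function(series, min_n = 20) {
  series <- tibble::as_tibble(series)
  check_columns(series, c("patient_id", "analyte", "median_value", "median_age"),
                "series")
  out <- list()
  for (an in unique(series$analyte)) {
    df <- series[series$analyte == an, ]
    df <- df[!is.na(df$median_value) & !is.na(df$median_age), ]
    if (nrow(df) < min_n) {
      warning("analyte '", an, "' has fewer than ", min_n,
              " complete observations; skipped", call. = FALSE)
      next
    }
    if (stats::var(df$median_age) == 0) {
      warning("analyte '", an, "' has zero age variance; transforming raw values",
              call. = FALSE)
      resid <- df$median_value
    } else {
      fit <- stats::lm(median_value ~ median_age, data = df)
      resid <- stats::residuals(fit)
    }
    out[[an]] <- tibble::tibble(patient_id = df$patient_id, analyte = an,
                                z = inverse_normal_transform(resid))
  }
  dplyr::bind_rows(out)
}

#' Rank-based inverse normal transform (Blom offsets)
#'
#' `z = qnorm((rank - 3/8) / (n + 1/4))` with average ranks for ties.
#'
#' @param x numeric vector.
#' @return transformed vector, same length and order.
#' @export
inverse_normal_transform <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Summarise lab values by algorithm group
#'
#' Median and interquartile bounds (25th/75th percentile, linear
#' interpolation) per algorithm x case/control group, optionally further
#' split by race/ethnicity stratum — the layout of the published lab
#' characterisation table.
#'
#' @param series tibble with `patient_id`, `analyte`, `median_value`.
#' @param cohorts a `cohort_assignment` from [build_cohorts()].
#' @param by_stratum also stratify by `stratum`?
#' @return tibble with `analyte`, `algorithm`, `group` (Cases/Controls),
#'   optional `stratum`, `n`, `median`, `q25`, `q75`.
#' @export
summarize_labs_by_group <- function(series, cohorts, by_stratum = FALSE) {
  series <- tibble::as_tibble(series)
  check_columns(series, c("patient_id", "analyte", "median_value"), "series")
  algs <- attr(cohorts, "case_algorithms")
  pieces <- list()
  for (alg in algs) {
    for (grp in c("Cases", "Controls")) {
      sel <- if (grp == "Cases") cohorts[[alg]] else cohorts$control
      ids <- cohorts$patient_id[!is.na(sel) & sel]
      df <- series[series$patient_id %in% ids, ]
      if (!nrow(df)) next
      if (by_stratum) {
        df <- dplyr::left_join(df, cohorts[, c("patient_id", "stratum")],
                               by = "patient_id")
        grouped <- dplyr::group_by(df, .data$analyte, .data$stratum)
      } else {
        grouped <- dplyr::group_by(df, .data$analyte)
      }
      pieces[[paste(alg, grp)]] <- grouped |>
        dplyr::summarise(
          n = dplyr::n(),
          median = stats::median(.data$median_value),
          q25 = stats::quantile(.data$median_value, 0.25, type = 7, names = FALSE),
          q75 = stats::quantile(.data$median_value, 0.75, type = 7, names = FALSE),
          .groups = "drop"
        ) |>
        dplyr::mutate(algorithm = alg, group = grp, .before = 1)
    }
  }
  dplyr::bind_rows(pieces)
}

#' Derive BMI rows from weight/height measurements
#'
#' Where a patient has weight (kg) and height (m) recorded on the same
#' date, a BMI row (kg/m2) is computed from the pair; recorded BMI rows
#' are kept as-is. Heights outside a sanity window of [1.2, 2.2] m are
#' ignored. Weight/height source rows are removed from the output.
#'
#' @param labs raw lab table (`patient_id`, `analyte`, `value`, `unit`,
#'   `date`), with weight/height analytes named "weight" and "height".
#' @return the lab table with derived `bmi` rows appended and
#'   weight/height rows removed.
#' @export
derive_bmi <- function(labs) {
  labs <- tibble::as_tibble(labs)
  check_columns(labs, c("patient_id", "analyte", "value", "unit", "date"), "labs")
  wh <- labs[labs$analyte %in% c("weight", "height"), ]
  rest <- labs[!labs$analyte %in% c("weight", "height"), ]
  if (!nrow(wh)) return(rest)
  wh$parsed <- suppressWarnings(as.numeric(wh$value))
  wide <- wh |>
    dplyr::filter(!is.na(.data$parsed)) |>
    dplyr::group_by(.data$patient_id, .data$date, .data$analyte) |>
    dplyr::summarise(parsed = stats::median(.data$parsed), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "parsed")
  if (!all(c("weight", "height") %in% names(wide))) return(rest)
  wide <- wide[!is.na(wide$weight) & !is.na(wide$height) &
                 wide$height >= 1.2 & wide$height <= 2.2, ]
  if (!nrow(wide)) return(rest)
  derived <- tibble::tibble(
    patient_id = wide$patient_id,
    analyte = "bmi",
    value = sprintf("%.2f", wide$weight / wide$height^2),
    unit = "kg/m2",
    date = wide$date
  )
  dplyr::bind_rows(rest, derived)
}
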