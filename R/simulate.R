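#' Simulation configuration for synthetic EHR populations
#'
#' Defines the generative model behind [generate_population()]: a female
#' population of reproductive age (11-44 years) with race/ethnicity strata,
#' a standard-normal polygenic risk score (PRS), a logistic liability model
#' linking the PRS to true PCOS status, symptom diagnosis codes and
#' clinical-note documentation arising with liability-dependent
#' probability, exclusion-code carriers among both cases and non-cases, and
#' log-normal lab values whose location shifts with case severity.
#'
#' Default calibration anchors: stratum weights follow the published
#' population mix (57% White, 11.5% African American, 4.3% Hispanic, the
#' rest other/unknown); base case rate 6.5% with odds ratio 1.3 per SD of
#' PRS; control median BMI about 24 kg/m2 rising to about 34 kg/m2 in
#' high-severity cases; insulin / estradiol / free-testosterone medians
#' near their published control values (13.65 mcU/mL, 55.5 pg/mL,
#' 3.0 pg/mL). Case symptom probabilities increase linearly in severity
#' (the standard-normal CDF of the PRS), which is what makes stricter
#' algorithm tiers select more severe - and genetically higher-risk -
#' cases.
#'
#' @param n_patients number of patients.
#' @param ... overrides for any top-level config entry (e.g.
#'   `beta_prs = 0`, `base_rate = 0.05`, or a full `symptom_model` /
#'   `lab_model` list).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_patients = 20000, ...) {
  cfg <- list(
    n_patients = n_patients,
    stratum_weights = c("NH White" = 0.567, "NH African American" = 0.115,
                        "Hispanic" = 0.043, "Other" = 0.275),
    age_range = c(11, 44),
    reference_date = as.Date("2018-01-01"),
    sex_other_rate = 0.02,
    base_rate = 0.065,
    beta_prs = log(1.3),
    symptom_model = list(
      case = list(
        polycystic_ovaries = c(0.35, 0.40),  # intercept, slope in severity
        hirsutism = c(0.20, 0.25),
        irregular_menses = c(0.50, 0.30),
        keyword = c(0.50, 0.40),
        exclusion = c(0.04, 0.00)
      ),
      noncase = list(
        polycystic_ovaries = 0.003,
        hirsutism = 0.012,
        irregular_menses = 0.030,
        keyword = 0.006,
        exclusion = 0.030
      )
    ),
    lab_model = list(
      bmi = list(control_median = 24.03, sdlog = 0.26,
                 case_shift = c(0.15, 0.28),
                 stratum_shift = c("NH African American" = 0.06,
                                   "Hispanic" = 0.02),
                 obs_rate = c(control = 0.75, case = 0.85),
                 unit = "kg/m2"),
      insulin = list(control_median = 13.65, sdlog = 0.65,
                     case_shift = c(0.10, 0.20),
                     stratum_shift = c("NH African American" = 0.05),
                     obs_rate = c(control = 0.05, case = 0.10),
                     unit = "mcU/mL"),
      estradiol = list(control_median = 55.5, sdlog = 0.75,
                       case_shift = c(0.00, 0.05),
                       stratum_shift = c("NH African American" = 0.05),
                       obs_rate = c(control = 0.06, case = 0.08),
                       unit = "pg/mL"),
      free_testosterone = list(control_median = 3.0, sdlog = 0.55,
                               case_shift = c(0.25, 0.35),
                               stratum_shift = c("NH African American" = 0.04),
                               obs_rate = c(control = 0.015, case = 0.06),
                               unit = "pg/mL")
    ),
    nonnumeric_rate = 0.005,
    discordant_unit_rate = 0.01,
    weight_height_rate = 0.08,
    distractor_note_rate = 0.05,
    off_whitelist_note_rate = 0.02
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown sim_config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  if (cfg$n_patients <= 0) stop("n_patients must be positive", call. = FALSE)
  if (abs(sum(cfg$stratum_weights) - 1) > 1e-8) {
    stop("stratum_weights must sum to 1", call. = FALSE)
  }
  if (!is.finite(cfg$beta_prs)) stop("beta_prs must be finite", call. = FALSE)
  if (cfg$base_rate <= 0 || cfg$base_rate >= 1) {
    stop("base_rate must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

SIM_FILLER_CODES <- list(
  ICD9 = c("465.9", "786.2", "724.2", "V70.0", "780.79"),
  ICD10 = c("J06.9", "R05", "M54.5", "Z00.00", "R53.83")
)

SIM_SYMPTOM_CODES <- list(
  polycystic_ovaries = data.frame(
    code = c("256.4", "E28.2"), icd_version = c("ICD9", "ICD10"),
    prob = c(0.3, 0.7)),
  hirsutism = data.frame(
    code = c("704.1", "L68.0"), icd_version = c("ICD9", "ICD10"),
    prob = c(0.45, 0.55)),
  irregular_menses = data.frame(
    code = c("626.0", "626.2", "626.4", "626.8", "626.9",
             "N91.0", "N91.1", "N91.2", "N92.5", "N92.6"),
    icd_version = rep(c("ICD9", "ICD10"), each = 5),
    prob = rep(0.1, 10)),
  exclusion = data.frame(
    code = c("255.2", "255.0", "253.1", "244.9",
             "E25.0", "E24.9", "E22.1", "E03.9"),
    icd_version = rep(c("ICD9", "ICD10"), each = 4),
    prob = rep(0.125, 8))
)

SIM_KEYWORD_TEMPLATES <- c(
  "Assessment: %s. Discussed lifestyle modification and management options.",
  "Patient with history of %s; will follow up in 3 months.",
  "Impression: clinical picture consistent with %s."
)

#' Generate a synthetic EHR population with ground truth
#'
#' Deterministic given `(config, seed)`. Each patient receives a stratum, a
#' birth date uniform over the configured age range (assessed at the
#' config's reference date), a PRS drawn N(0, 1), a true case indicator
#' drawn Bernoulli with logit equal to `qlogis(base_rate) +
#' beta_prs * PRS`, symptom codes / keyword notes / exclusion codes drawn
#' from the case- and severity-conditional probabilities, dated filler
#' codes anchoring a simulated record span, near-miss distractor notes
#' ("pcostatin") and off-whitelist PCOS mentions to exercise the keyword
#' matcher, and log-normal lab values with severity-dependent shifts. The
#' ground-truth table is returned separately and must never be shown to the
#' phenotyper.
#'
#' Randomness is split into named substreams (demographics, genetics,
#' symptoms, events, notes, labs) so changing one sub-model leaves the
#' others byte-reproducible.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed.
#' @return list with `population` (an [ehr_population()]) and `truth` (a
#'   tibble: `patient_id`, `true_case`, `liability`, `severity`, and
#'   per-symptom indicator flags).
#' @export
generate_population <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  ids <- sprintf("P%06d", seq_len(n))
  ref <- config$reference_date

  # demographics stream
  demo <- with_stream(seed, "demographics", {
    stratum <- sample(names(config$stratum_weights), n, replace = TRUE,
                      prob = config$stratum_weights)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    sex <- ifelse(stats::runif(n) < config$sex_other_rate, "other", "F")
    last_offset <- stats::runif(n, 0, 90)
    span_days <- pmin(stats::rgamma(n, shape = 2, scale = 2.2),
                      pmax(age - 1, 0.1), 12) * DAYS_PER_YEAR
    list(stratum = stratum, age = age, sex = sex,
         last_offset = last_offset, span_days = span_days)
  })
  race <- dplyr::case_when(
    demo$stratum == "NH White" ~ "White",
    demo$stratum == "NH African American" ~ "AfricanAmerican",
    demo$stratum == "Hispanic" ~ "White",
    TRUE ~ "Other"
  )
  hispanic <- demo$stratum == "Hispanic"
  birth_date <- ref - round(demo$age * DAYS_PER_YEAR)
  last_date <- ref - round(demo$last_offset)
  first_date <- last_date - round(demo$span_days)
  first_date <- pmax(first_date, birth_date + 30)

  # genetics stream
  gen <- with_stream(seed, "genetics", {
    prs <- stats::rnorm(n)
    pcs <- matrix(stats::rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    list(prs = prs, pcs = pcs)
  })
  ancestry <- ifelse(demo$stratum == "NH African American", "AFR", "EUR")

  liability <- stats::qlogis(config$base_rate) + config$beta_prs * gen$prs
  # case severity is the patient's percentile on the liability scale; with a
  # null genetic effect the liability is flat and severity degenerates to 0.5,
  # decoupling symptom draws from the PRS
  severity <- if (config$beta_prs != 0) {
    stats::pnorm((liability - mean(liability)) / stats::sd(liability))
  } else {
    rep(0.5, n)
  }

  # symptom stream
  sm <- config$symptom_model
  symp <- with_stream(seed, "symptoms", {
    true_case <- stats::rbinom(n, 1, stats::plogis(liability)) == 1
    draw_flag <- function(name) {
      p_case <- pmin(pmax(sm$case[[name]][1] + sm$case[[name]][2] * severity, 0), 1)
      p <- ifelse(true_case, p_case, sm$noncase[[name]])
      stats::runif(n) < p
    }
    list(true_case = true_case,
         pco = draw_flag("polycystic_ovaries"),
         hirsutism = draw_flag("hirsutism"),
         irregular = draw_flag("irregular_menses"),
         keyword = draw_flag("keyword"),
         exclusion = draw_flag("exclusion"))
  })

  # code-event stream
  codes <- with_stream(seed, "events", {
    pieces <- list()
    # two filler anchors pin the record span for every patient
    anchor_codes <- sample(length(SIM_FILLER_CODES$ICD10) * 2, 2 * n,
                           replace = TRUE)
    all_filler <- rbind(
      data.frame(code = SIM_FILLER_CODES$ICD9, icd_version = "ICD9"),
      data.frame(code = SIM_FILLER_CODES$ICD10, icd_version = "ICD10"))
    pieces$anchors <- tibble::tibble(
      patient_id = rep(ids, 2),
      code = all_filler$code[anchor_codes],
      icd_version = all_filler$icd_version[anchor_codes],
      date = c(first_date, last_date))
    # extra filler visits
    n_extra <- stats::rpois(n, 3)
    idx <- rep(seq_len(n), n_extra)
    if (length(idx)) {
      pick <- sample(nrow(all_filler), length(idx), replace = TRUE)
      pieces$filler <- tibble::tibble(
        patient_id = ids[idx],
        code = all_filler$code[pick],
        icd_version = all_filler$icd_version[pick],
        date = first_date[idx] +
          round(stats::runif(length(idx)) * as.numeric(last_date - first_date)[idx]))
    }
    emit_symptom <- function(flag, family) {
      who <- which(flag)
      if (!length(who)) return(NULL)
      n_ev <- 1 + stats::rbinom(length(who), 2, 0.4)
      idx <- rep(who, n_ev)
      fam <- SIM_SYMPTOM_CODES[[family]]
      pick <- sample(nrow(fam), length(idx), replace = TRUE, prob = fam$prob)
      tibble::tibble(
        patient_id = ids[idx],
        code = fam$code[pick],
        icd_version = fam$icd_version[pick],
        date = first_date[idx] +
          round(stats::runif(length(idx)) * as.numeric(last_date - first_date)[idx]))
    }
    pieces$pco <- emit_symptom(symp$pco, "polycystic_ovaries")
    pieces$hirsutism <- emit_symptom(symp$hirsutism, "hirsutism")
    pieces$irregular <- emit_symptom(symp$irregular, "irregular_menses")
    pieces$exclusion <- emit_symptom(symp$exclusion, "exclusion")
    dplyr::arrange(dplyr::bind_rows(pieces), .data$patient_id, .data$date,
                   .data$code)
  })

  # note stream
  notes <- with_stream(seed, "notes", {
    pieces <- list()
    who <- which(symp$keyword)
    if (length(who)) {
      n_notes <- 1 + stats::rbinom(length(who), 1, 0.4)
      idx <- rep(who, n_notes)
      kw <- sample(DEFAULT_KEYWORDS, length(idx), replace = TRUE,
                   prob = c(0.3, 0.55, 0.15))
      tmpl <- sample(SIM_KEYWORD_TEMPLATES, length(idx), replace = TRUE)
      pieces$keyword <- tibble::tibble(
        patient_id = ids[idx],
        note_type = sample(DEFAULT_NOTE_TYPES, length(idx), replace = TRUE),
        date = first_date[idx] +
          round(stats::runif(length(idx)) * as.numeric(last_date - first_date)[idx]),
        text = sprintf(tmpl, kw))
    }
    distract <- which(stats::runif(n) < config$distractor_note_rate)
    if (length(distract)) {
      pieces$distractor <- tibble::tibble(
        patient_id = ids[distract],
        note_type = "outpatient note",
        date = last_date[distract],
        text = "Medication review: pcostatin 10 mg daily continued; apcot clinic follow-up.")
    }
    off <- which(stats::runif(n) < config$off_whitelist_note_rate)
    if (length(off)) {
      pieces$off_whitelist <- tibble::tibble(
        patient_id = ids[off],
        note_type = "radiology report",
        date = last_date[off],
        text = "Pelvic ultrasound reviewed; PCOS suspected, correlate clinically.")
    }
    routine <- which(stats::runif(n) < 0.3)
    if (length(routine)) {
      pieces$routine <- tibble::tibble(
        patient_id = ids[routine],
        note_type = "outpatient note",
        date = first_date[routine],
        text = "Routine visit; no acute complaints.")
    }
    dplyr::arrange(dplyr::bind_rows(pieces), .data$patient_id, .data$date)
  })

  # lab stream
  labs <- with_stream(seed, "labs", {
    pieces <- list()
    for (an in names(config$lab_model)) {
      lm_ <- config$lab_model[[an]]
      p_obs <- ifelse(symp$true_case, lm_$obs_rate[["case"]],
                      lm_$obs_rate[["control"]])
      who <- which(stats::runif(n) < p_obs)
      if (!length(who)) next
      n_meas <- 1 + stats::rpois(length(who), 0.8)
      idx <- rep(who, n_meas)
      shift <- rep(0, n)
      for (st in names(lm_$stratum_shift)) {
        shift[demo$stratum == st] <- shift[demo$stratum == st] +
          lm_$stratum_shift[[st]]
      }
      case_shift <- ifelse(symp$true_case,
                           lm_$case_shift[1] + lm_$case_shift[2] * severity, 0)
      meanlog <- log(lm_$control_median) + shift + case_shift
      value <- stats::rlnorm(length(idx), meanlog[idx], lm_$sdlog)
      unit <- rep(lm_$unit, length(idx))
      if (an == "insulin") {
        disc <- stats::runif(length(idx)) < config$discordant_unit_rate
        unit[disc] <- "pmol/L"
        value[disc] <- value[disc] * 6.945
      }
      raw <- sprintf("%.2f", value)
      raw[stats::runif(length(idx)) < config$nonnumeric_rate] <- "QNS"
      pieces[[an]] <- tibble::tibble(
        patient_id = ids[idx],
        analyte = an,
        value = raw,
        unit = unit,
        date = first_date[idx] +
          round(stats::runif(length(idx)) * as.numeric(last_date - first_date)[idx]))
    }
    labs <- dplyr::bind_rows(pieces)
    # a slice of patients record weight/height pairs instead of a BMI row
    if (nrow(labs) && config$weight_height_rate > 0) {
      bmi_rows <- which(labs$analyte == "bmi")
      wh_patients <- unique(labs$patient_id[bmi_rows])
      wh_patients <- wh_patients[stats::runif(length(wh_patients)) <
                                   config$weight_height_rate]
      conv <- labs$patient_id %in% wh_patients & labs$analyte == "bmi"
      if (any(conv)) {
        src <- labs[conv, ]
        height <- pmin(pmax(stats::rnorm(nrow(src), 1.63, 0.07), 1.3), 2.1)
        bmi_val <- suppressWarnings(as.numeric(src$value))
        ok <- !is.na(bmi_val)
        src <- src[ok, ]; height <- height[ok]; bmi_val <- bmi_val[ok]
        wh <- dplyr::bind_rows(
          tibble::tibble(patient_id = src$patient_id, analyte = "weight",
                         value = sprintf("%.1f", bmi_val * height^2),
                         unit = "kg", date = src$date),
          tibble::tibble(patient_id = src$patient_id, analyte = "height",
                         value = sprintf("%.2f", height),
                         unit = "m", date = src$date))
        labs <- dplyr::bind_rows(labs[!conv, ], wh)
      }
    }
    dplyr::arrange(labs, .data$patient_id, .data$analyte, .data$date)
  })

  patients <- tibble::tibble(
    patient_id = ids, birth_date = birth_date, sex = demo$sex,
    race = race, hispanic = hispanic)
  genetics <- tibble::tibble(patient_id = ids, prs = gen$prs)
  genetics <- dplyr::bind_cols(genetics, tibble::as_tibble(gen$pcs))
  genetics$ancestry <- ancestry

  population <- ehr_population(patients, codes, notes, labs, genetics)
  truth <- tibble::tibble(
    patient_id = ids,
    true_case = symp$true_case,
    liability = liability,
    severity = severity,
    pco_code = symp$pco,
    hirsutism_code = symp$hirsutism,
    irregular_menses_code = symp$irregular,
    keyword_documented = symp$keyword,
    exclusion_code = symp$exclusion
  )
  list(population = population, truth = truth)
}

#' Draw a chart-review sample of algorithm-defined cases
#'
#' Simple random sample without replacement of `n` algorithm-identified
#' cases per algorithm, paired with the ground-truth label — the synthetic
#' analogue of pulling charts for manual review.
#'
#' @param truth ground-truth tibble from [generate_population()].
#' @param assignments a `cohort_assignment` from [build_cohorts()].
#' @param algorithms algorithm names to sample from (defaults to all case
#'   algorithms in `assignments`).
#' @param n charts per algorithm (default 50).
#' @param seed integer seed.
#' @return tibble with `algorithm`, `patient_id`, `true_case`.
#' @export
generate_chart_review_sample <- function(truth, assignments,
                                         algorithms = NULL, n = 50,
                                         seed = 1L) {
  algorithms <- algorithms %||% attr(assignments, "case_algorithms")
  out <- with_stream(seed, "chart_review", {
    pieces <- lapply(algorithms, function(alg) {
      lab <- assignments[[alg]]
      cases <- assignments$patient_id[!is.na(lab) & lab]
      if (n > length(cases)) {
        stop("algorithm '", alg, "' has only ", length(cases),
             " cases; cannot sample ", n, call. = FALSE)
      }
      tibble::tibble(algorithm = alg,
                     patient_id = sort(sample(cases, n)))
    })
    dplyr::bind_rows(pieces)
  })
  dplyr::left_join(out, truth[, c("patient_id", "true_case")], by = "patient_id")
}

#' Simulate a PRS case-control sample from the liability model
#'
#' Draws the genetics/liability submodel alone: PRS ~ N(0, 1), case status
#' Bernoulli with logit `qlogis(base_rate) + log(or_per_sd) * PRS`, then a
#' fixed number of cases and controls sampled from the pool, with
#' pure-noise principal components attached. Under the logistic liability
#' model, case-control sampling leaves the odds ratio per SD intact, so
#' the generative `or_per_sd` is the estimand for a logistic refit. Used
#' for parameter-recovery and type-I-error studies of the association
#' models without building full EHR populations.
#'
#' @param n_cases,n_controls sample sizes.
#' @param or_per_sd generative odds ratio per SD of PRS.
#' @param base_rate population case rate.
#' @param n_pcs number of noise principal components.
#' @param seed integer seed.
#' @return tibble with `case`, `prs`, `pc1..pcK`.
#' @export
simulate_prs_case_control <- function(n_cases, n_controls, or_per_sd = 1.3,
                                      base_rate = 0.065, n_pcs = 10,
                                      seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0, or_per_sd > 0)
  with_stream(seed, "prs_case_control", {
    prs <- numeric(0); case <- logical(0)
    while (sum(case) < n_cases || sum(!case) < n_controls) {
      m <- max(5000, ceiling(1.5 * (n_cases / base_rate)))
      new_prs <- stats::rnorm(m)
      p <- stats::plogis(stats::qlogis(base_rate) + log(or_per_sd) * new_prs)
      prs <- c(prs, new_prs)
      case <- c(case, stats::rbinom(m, 1, p) == 1)
    }
    take <- c(sample(which(case), n_cases), sample(which(!case), n_controls))
    df <- tibble::tibble(case = case[take], prs = prs[take])
    pcs <- matrix(stats::rnorm(length(take) * n_pcs), ncol = n_pcs,
                  dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))
    dplyr::bind_cols(df, tibble::as_tibble(pcs))
  })
}

#' Write a ground-truth table
#'
#' @param truth tibble from [generate_population()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}
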