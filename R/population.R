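#' EHR population container
#'
#' Bundles the flat tables of an electronic-health-record extract into a
#' single object: one row per patient plus event tables of dated diagnosis
#' codes, typed clinical notes, laboratory measurements and (optionally)
#' per-patient genetic summaries (polygenic risk score, principal
#' components, genetic ancestry).
#'
#' Expected columns:
#' * `patients`: `patient_id`, `birth_date` (Date), `sex` ("F" or "other"),
#'   `race` ("White", "AfricanAmerican", "Hispanic", "Other"), `hispanic`
#'   (logical ethnicity flag).
#' * `codes`: `patient_id`, `code`, `icd_version` ("ICD9"/"ICD10"), `date`.
#' * `notes`: `patient_id`, `note_type`, `date`, `text`.
#' * `labs`: `patient_id`, `analyte`, `value` (raw character; may be
#'   non-numeric), `unit`, `date`.
#' * `genetics` (optional): `patient_id`, `prs`, `pc1`..`pc10`, `ancestry`
#'   ("EUR"/"AFR").
#'
#' The constructor enforces the container invariants: unique patient ids,
#' event patient ids present in the patient table, and event dates on or
#' after birth. Use [read_population()] for tolerant file loading that
#' drops and counts invalid rows instead of failing.
#'
#' @param patients,codes,notes,labs data frames as described above.
#' @param genetics optional data frame as described above.
#' @return an object of class `ehr_population`.
#' @seealso [read_population()], [write_population()], [generate_population()]
#' @export
ehr_population <- function(patients, codes, notes, labs, genetics = NULL) {
  patients <- tibble::as_tibble(patients)
  codes <- tibble::as_tibble(codes)
  notes <- tibble::as_tibble(notes)
  labs <- tibble::as_tibble(labs)

  check_columns(patients, c("patient_id", "birth_date", "sex", "race", "hispanic"),
                "patients")
  check_columns(codes, c("patient_id", "code", "icd_version", "date"), "codes")
  check_columns(notes, c("patient_id", "note_type", "date", "text"), "notes")
  check_columns(labs, c("patient_id", "analyte", "value", "unit", "date"), "labs")

  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  for (nm in c("codes", "notes", "labs")) {
    tab <- get(nm)
    if (nrow(tab) && !all(tab$patient_id %in% patients$patient_id)) {
      stop("table '", nm, "' refers to patient_ids absent from patients",
           call. = FALSE)
    }
  }
  birth <- stats::setNames(patients$birth_date, patients$patient_id)
  for (nm in c("codes", "notes", "labs")) {
    tab <- get(nm)
    if (nrow(tab) && any(tab$date < birth[tab$patient_id])) {
      stop("table '", nm, "' has event dates before birth_date", call. = FALSE)
    }
  }
  if (nrow(codes) && !all(codes$icd_version %in% c("ICD9", "ICD10"))) {
    stop("icd_version must be 'ICD9' or 'ICD10'", call. = FALSE)
  }
  if (!is.null(genetics)) {
    genetics <- tibble::as_tibble(genetics)
    check_columns(genetics, c("patient_id", "prs", paste0("pc", 1:10), "ancestry"),
                  "genetics")
    if (any(!is.finite(genetics$prs))) {
      stop("non-finite PRS values in genetics table", call. = FALSE)
    }
  }

  patients$stratum <- resolve_stratum(patients$race, patients$hispanic)
  structure(
    list(patients = patients, codes = codes, notes = notes, labs = labs,
         genetics = genetics),
    class = "ehr_population"
  )
}

check_columns <- function(df, required, table_name) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("table '", table_name, "' is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Resolve race/ethnicity into analysis strata
#'
#' A recorded Hispanic ethnicity flag takes precedence over the race field,
#' so Hispanic White and Hispanic African American patients both land in the
#' Hispanic stratum; non-Hispanic patients split by race, with unknown race
#' retained as "Other" (kept in overall totals, excluded from race-stratified
#' analyses).
#'
#' @param race character vector.
#' @param hispanic logical vector.
#' @return character vector with levels "NH White", "NH African American",
#'   "Hispanic", "Other".
#' @export
resolve_stratum <- function(race, hispanic) {
  out <- rep("Other", length(race))
  out[!is.na(race) & race == "White"] <- "NH White"
  out[!is.na(race) & race == "AfricanAmerican"] <- "NH African American"
  out[!is.na(hispanic) & hispanic] <- "Hispanic"
  out
}

#' @export
print.ehr_population <- function(x, ...) {
  cat("<ehr_population>\n")
  cat("  patients:", nrow(x$patients), "\n")
  cat("  code events:", nrow(x$codes), "\n")
  cat("  notes:", nrow(x$notes), "\n")
  cat("  lab measurements:", nrow(x$labs), "\n")
  cat("  genetics:", if (is.null(x$genetics)) "absent" else
    paste(nrow(x$genetics), "patients"), "\n")
  invisible(x)
}

#' Age in years at a given date
#'
#' Computed as `(date - birth_date) / 365.25`; the 365.25-day year absorbs
#' leap days, matching conventional EHR practice.
#'
#' @param birth_date Date vector of birth dates.
#' @param date Date vector (recycled) at which age is assessed.
#' @return numeric vector of ages in years.
#' @export
age_at <- function(birth_date, date) {
  if (any(date < birth_date)) {
    stop("date precedes birth_date", call. = FALSE)
  }
  as.numeric(date - birth_date) / DAYS_PER_YEAR
}

#' Per-patient record features derived from code events
#'
#' For each patient: number of distinct calendar days with a diagnosis code,
#' first/last code dates, record length in years (last minus first code
#' date; 0 for a single event; NA with no events), age at the last code
#' event, and the "medical home" indicator (codes on at least 5 separate
#' days spanning at least a 3-year period), a data-sufficiency filter used
#' before sensitivity/specificity evaluation.
#'
#' @param population an [ehr_population()].
#' @return a tibble with one row per patient.
#' @export
patient_features <- function(population) {
  stopifnot(inherits(population, "ehr_population"))
  codes <- dplyr::distinct(population$codes, .data$patient_id, .data$code,
                           .data$icd_version, .data$date)
  by_patient <- if (nrow(codes)) {
    codes |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(
        n_code_days = dplyr::n_distinct(.data$date),
        first_code_date = min(.data$date),
        last_code_date = max(.data$date),
        .groups = "drop"
      )
  } else {
    tibble::tibble(patient_id = character(), n_code_days = integer(),
                   first_code_date = as.Date(character()),
                   last_code_date = as.Date(character()))
  }
  population$patients |>
    dplyr::select("patient_id", "birth_date", "sex", "stratum") |>
    dplyr::left_join(by_patient, by = "patient_id") |>
    dplyr::mutate(
      n_code_days = dplyr::coalesce(.data$n_code_days, 0L),
      record_length_years = as.numeric(.data$last_code_date - .data$first_code_date) /
        DAYS_PER_YEAR,
      age_at_last_code = as.numeric(.data$last_code_date - .data$birth_date) /
        DAYS_PER_YEAR,
      medical_home = .data$n_code_days >= 5 &
        !is.na(.data$record_length_years) & .data$record_length_years >= 3
    )
}

#' Record length in years
#'
#' Span between first and last diagnosis-code event; 0 for a single event,
#' NA for patients with no code events (an explicit missing marker, never a
#' silent zero).
#'
#' @param population an [ehr_population()].
#' @return tibble with `patient_id` and `record_length_years`.
#' @export
record_length_years <- function(population) {
  patient_features(population)[, c("patient_id", "record_length_years")]
}

#' Medical-home indicator
#'
#' TRUE iff the patient has diagnosis codes on at least 5 distinct calendar
#' days and the span between first and last code date is at least 3 years
#' (1095.75 days under the 365.25-day year).
#'
#' @param population an [ehr_population()].
#' @return tibble with `patient_id` and logical `medical_home`.
#' @export
is_medical_home <- function(population) {
  patient_features(population)[, c("patient_id", "medical_home")]
}

# --- file I/O -------------------------------------------------------------

pop_file_names <- c(patients = "patients.tsv", codes = "codes.tsv",
                    notes = "notes.tsv", labs = "labs.tsv",
                    genetics = "genetics.tsv")

#' Write a population to a directory of TSV files
#'
#' Emits `patients.tsv`, `codes.tsv`, `notes.tsv`, `labs.tsv` and, when
#' genetics are present, `genetics.tsv` (UTF-8, tab-separated, header row,
#' free text quoted).
#'
#' @param population an [ehr_population()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "ehr_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pats <- dplyr::select(population$patients, -dplyr::any_of("stratum"))
  readr::write_tsv(pats, file.path(dir, "patients.tsv"))
  readr::write_tsv(population$codes, file.path(dir, "codes.tsv"))
  readr::write_tsv(population$notes, file.path(dir, "notes.tsv"), quote = "needed")
  readr::write_tsv(population$labs, file.path(dir, "labs.tsv"))
  if (!is.null(population$genetics)) {
    readr::write_tsv(population$genetics, file.path(dir, "genetics.tsv"))
  }
  invisible(dir)
}

#' Read a population from a directory of TSV files
#'
#' Tolerant loader: rows with unparseable dates, event dates before birth,
#' blank codes, or patient ids absent from the patient table are dropped,
#' counted and reported (see the `rejections` attribute of the result). A
#' missing mandatory column is a hard error naming the column. Missing or
#' empty event files yield empty tables, not errors.
#'
#' @param dir directory containing `patients.tsv` etc., as written by
#'   [write_population()].
#' @param quiet suppress the rejection-count message.
#' @return an [ehr_population()] with attribute `rejections`, a named count
#'   of dropped rows per table.
#' @export
read_population <- function(dir, quiet = FALSE) {
  read_tab <- function(name, col_types) {
    path <- file.path(dir, pop_file_names[[name]])
    if (!file.exists(path) || file.size(path) == 0) {
      return(NULL)
    }
    # readr warns when col_types name a column the file lacks; the missing
    # column is reported as a hard error by check_columns instead
    df <- suppressWarnings(
      readr::read_tsv(path, col_types = col_types, progress = FALSE))
    # strip readr's spec subclass so round-tripped tables compare clean
    tibble::as_tibble(as.data.frame(df))
  }

  patients <- read_tab("patients", readr::cols(
    patient_id = readr::col_character(), birth_date = readr::col_date(),
    sex = readr::col_character(), race = readr::col_character(),
    hispanic = readr::col_logical()))
  if (is.null(patients)) {
    patients <- tibble::tibble(patient_id = character(), birth_date = as.Date(character()),
                               sex = character(), race = character(), hispanic = logical())
  }
  check_columns(patients, c("patient_id", "birth_date", "sex", "race", "hispanic"),
                "patients")

  rejections <- c(patients = 0L, codes = 0L, notes = 0L, labs = 0L, genetics = 0L)
  bad <- is.na(patients$birth_date) | is.na(patients$patient_id) |
    duplicated(patients$patient_id)
  rejections["patients"] <- sum(bad)
  patients <- patients[!bad, ]
  birth <- stats::setNames(patients$birth_date, patients$patient_id)

  filter_events <- function(df, name, extra_bad = FALSE) {
    if (is.null(df) || !nrow(df)) return(list(df = df, dropped = 0L))
    bad <- is.na(df$date) | !(df$patient_id %in% patients$patient_id) | extra_bad
    bad[!bad] <- df$date[!bad] < birth[df$patient_id[!bad]]
    list(df = df[!bad, ], dropped = sum(bad))
  }

  codes <- read_tab("codes", readr::cols(
    patient_id = readr::col_character(), code = readr::col_character(),
    icd_version = readr::col_character(), date = readr::col_date()))
  check_columns(codes %||% tibble::tibble(patient_id = character(), code = character(),
                                          icd_version = character(),
                                          date = as.Date(character())),
                c("patient_id", "code", "icd_version", "date"), "codes")
  if (!is.null(codes)) {
    res <- filter_events(codes, "codes",
                         extra_bad = is.na(codes$code) | codes$code == "" |
                           !(codes$icd_version %in% c("ICD9", "ICD10")))
    codes <- res$df; rejections["codes"] <- res$dropped
  } else {
    codes <- tibble::tibble(patient_id = character(), code = character(),
                            icd_version = character(), date = as.Date(character()))
  }

  notes <- read_tab("notes", readr::cols(
    patient_id = readr::col_character(), note_type = readr::col_character(),
    date = readr::col_date(), text = readr::col_character()))
  if (!is.null(notes)) {
    res <- filter_events(notes, "notes")
    notes <- res$df; rejections["notes"] <- res$dropped
  } else {
    notes <- tibble::tibble(patient_id = character(), note_type = character(),
                            date = as.Date(character()), text = character())
  }

  labs <- read_tab("labs", readr::cols(
    patient_id = readr::col_character(), analyte = readr::col_character(),
    value = readr::col_character(), unit = readr::col_character(),
    date = readr::col_date()))
  if (!is.null(labs)) {
    res <- filter_events(labs, "labs")
    labs <- res$df; rejections["labs"] <- res$dropped
  } else {
    labs <- tibble::tibble(patient_id = character(), analyte = character(),
                           value = character(), unit = character(),
                           date = as.Date(character()))
  }

  genetics <- read_tab("genetics", readr::cols(
    patient_id = readr::col_character(), ancestry = readr::col_character(),
    .default = readr::col_double()))
  if (!is.null(genetics)) {
    bad <- !(genetics$patient_id %in% patients$patient_id) | !is.finite(genetics$prs)
    rejections["genetics"] <- sum(bad)
    genetics <- genetics[!bad, ]
  }

  if (!quiet && sum(rejections) > 0) {
    message("read_population: dropped invalid rows - ",
            paste(names(rejections), rejections, sep = ": ", collapse = ", "))
  }
  pop <- ehr_population(patients, codes, notes, labs, genetics)
  attr(pop, "rejections") <- rejections
  pop
}
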