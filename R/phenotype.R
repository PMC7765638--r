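#' Match patients against a diagnosis code set
#'
#' A patient matches when at least one code event equals an `exact` member
#' (string equality within the member's ICD version) or starts with a
#' `prefix` member's pattern (code-family matching, e.g. every 626.x code),
#' again within the ICD version. Matching is invariant to event order and
#' duplicate events.
#'
#' @param population an [ehr_population()].
#' @param cs a [code_set()].
#' @return tibble with `patient_id` and logical `matched`, one row per
#'   patient in the population.
#' @export
matches_code_set <- function(population, cs) {
  stopifnot(inherits(population, "ehr_population"), inherits(cs, "code_set"))
  hits <- code_event_matches(population$codes, cs)
  matched_ids <- unique(population$codes$patient_id[hits])
  tibble::tibble(
    patient_id = population$patients$patient_id,
    matched = population$patients$patient_id %in% matched_ids
  )
}

# Row-wise logical: does each code event match any member of the set?
code_event_matches <- function(codes, cs) {
  if (!nrow(codes)) return(logical(0))
  hit <- rep(FALSE, nrow(codes))
  for (i in seq_len(nrow(cs$members))) {
    m <- cs$members[i, ]
    same_version <- codes$icd_version == m$icd_version
    if (m$match_mode == "exact") {
      hit <- hit | (same_version & codes$code == m$pattern)
    } else {
      hit <- hit | (same_version & startsWith(codes$code, m$pattern))
    }
  }
  hit
}

#' Detect PCOS keywords in whitelisted clinical notes
#'
#' Note types are compared after case-folding and whitespace normalisation
#' against the whitelist. Keyword matching is case-insensitive; with
#' `mode = "token"` (the default) single-word keywords such as "PCOS" and
#' "PCO" must appear as whole alphanumeric tokens (so "PCO" does not fire
#' inside "pcostatin"), and multi-word keywords match as
#' whitespace-normalised phrases with token boundaries at both ends. With
#' `mode = "substring"` plain case-insensitive substring search is used.
#'
#' @param population an [ehr_population()].
#' @param keywords character vector of keywords.
#' @param note_types whitelist of note types.
#' @param mode `"token"` (default) or `"substring"`.
#' @return tibble with `patient_id` and logical `has_keyword`.
#' @export
has_keyword <- function(population, keywords = DEFAULT_KEYWORDS,
                        note_types = DEFAULT_NOTE_TYPES,
                        mode = c("token", "substring")) {
  stopifnot(inherits(population, "ehr_population"))
  mode <- match.arg(mode)
  notes <- population$notes
  hit_ids <- character(0)
  if (nrow(notes)) {
    type_norm <- normalize_ws(tolower(notes$note_type))
    allowed <- type_norm %in% normalize_ws(tolower(note_types))
    in_scope <- notes[allowed, ]
    if (nrow(in_scope)) {
      hit <- rep(FALSE, nrow(in_scope))
      text <- in_scope$text
      for (kw in keywords) {
        if (mode == "token") {
          hit <- hit | grepl(keyword_regex(kw), text, perl = TRUE,
                             ignore.case = TRUE)
        } else {
          hit <- hit | grepl(tolower(kw), tolower(text), fixed = TRUE)
        }
      }
      hit_ids <- unique(in_scope$patient_id[hit])
    }
  }
  tibble::tibble(
    patient_id = population$patients$patient_id,
    has_keyword = population$patients$patient_id %in% hit_ids
  )
}

normalize_ws <- function(x) {
  gsub("\\s+", " ", trimws(x))
}

# Token/phrase regex for one keyword: alphanumeric boundaries around the
# whole keyword; internal whitespace matches any whitespace run.
keyword_regex <- function(kw) {
  parts <- strsplit(normalize_ws(kw), " ", fixed = TRUE)[[1]]
  escaped <- vapply(parts, function(p) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p),
                    character(1))
  paste0("(?<![[:alnum:]])", paste(escaped, collapse = "\\s+"), "(?![[:alnum:]])")
}

# Per-patient boolean flags for every code set plus the keyword predicate
# of each algorithm that needs one. Internal engine behind build_cohorts.
phenotype_flags <- function(population, algorithms, keyword_mode = "token") {
  stopifnot(inherits(algorithms, "algorithm_set"))
  flags <- tibble::tibble(patient_id = population$patients$patient_id)
  for (nm in names(algorithms$code_sets)) {
    flags[[nm]] <- matches_code_set(population, algorithms$code_sets[[nm]])$matched
  }
  # one keyword column per distinct (keywords, note_types) spec
  kw_cols <- list()
  for (alg in algorithms$algorithms) {
    if (!alg$keyword_required) next
    key <- paste(c(alg$keywords, "|", alg$note_types), collapse = "\x1f")
    if (is.null(kw_cols[[key]])) {
      kw_cols[[key]] <- has_keyword(population, alg$keywords, alg$note_types,
                                    mode = keyword_mode)$has_keyword
    }
  }
  attr(flags, "keyword_cols") <- kw_cols
  flags
}

keyword_key <- function(alg) {
  paste(c(alg$keywords, "|", alg$note_types), collapse = "\x1f")
}

#' Assign case, control and eligibility labels for a population
#'
#' Applies the eligibility filter once (female, age within the algorithm
#' age window, assessed at the most recent code event by default), then
#' labels every eligible patient under each case algorithm (inclusion logic
#' AND no exclusion code AND, where required, a keyword in a whitelisted
#' note) and under the control rule (no exclusion code and no inclusion
#' code of any kind). Patients that are ineligible get NA labels.
#'
#' @param population an [ehr_population()].
#' @param algorithms an [algorithm_set()]; defaults to
#'   [default_algorithms()].
#' @param age_basis `"last_event"` (age at most recent code event, default)
#'   or `"any_event"` (eligible if any code event falls in the window).
#' @param keyword_mode passed to [has_keyword()].
#' @return object of class `cohort_assignment`: a tibble with `patient_id`,
#'   `stratum`, `eligible`, `age`, one logical column per case algorithm,
#'   and logical `control`.
#' @seealso [cohort_summary()], [classify_patient()]
#' @export
build_cohorts <- function(population, algorithms = default_algorithms(),
                          age_basis = c("last_event", "any_event"),
                          keyword_mode = "token") {
  age_basis <- match.arg(age_basis)
  feats <- patient_features(population)
  flags <- phenotype_flags(population, algorithms, keyword_mode)
  kw_cols <- attr(flags, "keyword_cols")

  case_algs <- Filter(function(a) !is.na(a$inclusion), algorithms$algorithms)
  control_algs <- Filter(function(a) is.na(a$inclusion), algorithms$algorithms)

  # all age windows are required to agree for a single eligibility pass
  ranges <- unique(lapply(algorithms$algorithms, function(a) a$age_range))
  if (length(ranges) > 1) {
    stop("algorithms disagree on age_range; build_cohorts applies one filter",
         call. = FALSE)
  }
  rng <- ranges[[1]]

  if (age_basis == "last_event") {
    in_age <- !is.na(feats$age_at_last_code) &
      feats$age_at_last_code >= rng[1] & feats$age_at_last_code <= rng[2]
    age <- feats$age_at_last_code
  } else {
    codes <- dplyr::left_join(population$codes,
                              population$patients[, c("patient_id", "birth_date")],
                              by = "patient_id")
    codes$age <- as.numeric(codes$date - codes$birth_date) / DAYS_PER_YEAR
    ok <- codes$patient_id[codes$age >= rng[1] & codes$age <= rng[2]]
    in_age <- feats$patient_id %in% unique(ok)
    age <- feats$age_at_last_code
  }
  eligible <- feats$sex == "F" & in_age

  out <- tibble::tibble(
    patient_id = feats$patient_id,
    stratum = feats$stratum,
    eligible = eligible,
    age = age
  )

  # inclusion-set union used by the control rule: every set referenced in
  # any case algorithm's inclusion expression
  inclusion_sets <- unique(unlist(lapply(case_algs, function(a) {
    all.vars(str2lang(a$inclusion))
  })))

  mask <- function(x) ifelse(eligible, x, NA)
  for (alg in case_algs) {
    incl <- eval(str2lang(alg$inclusion), envir = flags)
    excl <- flags[[alg$exclusion]]
    lab <- incl & !excl
    if (alg$keyword_required) {
      lab <- lab & kw_cols[[keyword_key(alg)]]
    }
    out[[alg$name]] <- mask(lab)
  }
  if (length(control_algs)) {
    ctl <- control_algs[[1]]
    any_inclusion <- Reduce(`|`, lapply(inclusion_sets, function(nm) flags[[nm]]),
                            rep(FALSE, nrow(flags)))
    out$control <- mask(!flags[[ctl$exclusion]] & !any_inclusion)
  }
  structure(out, class = c("cohort_assignment", class(out)),
            case_algorithms = names(case_algs))
}

#' Classify one patient under one algorithm
#'
#' Convenience wrapper over [build_cohorts()] for a single patient; errors
#' if the patient is ineligible (callers must pre-filter to eligible
#' females in the age window).
#'
#' @param population an [ehr_population()].
#' @param patient_id patient to classify.
#' @param algorithm algorithm name (e.g. `"keyword_strict"`).
#' @param algorithms an [algorithm_set()].
#' @param ... passed to [build_cohorts()].
#' @return `"case"` or `"not_case"`.
#' @export
classify_patient <- function(population, patient_id, algorithm,
                             algorithms = default_algorithms(), ...) {
  cohorts <- build_cohorts(population, algorithms, ...)
  row <- cohorts[cohorts$patient_id == patient_id, ]
  if (!nrow(row)) stop("unknown patient_id: ", patient_id, call. = FALSE)
  if (!isTRUE(row$eligible)) {
    stop("patient ", patient_id, " is ineligible (not female or outside the ",
         "age window); pre-filter before classification", call. = FALSE)
  }
  if (!algorithm %in% names(cohorts)) {
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  }
  if (isTRUE(row[[algorithm]])) "case" else "not_case"
}

#' Cohort summary counts
#'
#' Case/control counts overall and per race/ethnicity stratum, in the
#' layout of the descriptive tables (algorithms as columns, strata as
#' rows).
#'
#' @param cohorts a `cohort_assignment` from [build_cohorts()].
#' @return tibble with `group` ("Overall" plus each stratum) and one count
#'   column per algorithm and for controls.
#' @export
cohort_summary <- function(cohorts) {
  algs <- c(attr(cohorts, "case_algorithms"),
            if ("control" %in% names(cohorts)) "control")
  count_in <- function(rows) {
    vapply(algs, function(a) sum(cohorts[[a]][rows], na.rm = TRUE), integer(1))
  }
  groups <- c("Overall", "NH White", "NH African American", "Hispanic")
  rows <- lapply(groups, function(g) {
    sel <- if (g == "Overall") rep(TRUE, nrow(cohorts)) else cohorts$stratum == g
    tibble::as_tibble_row(c(list(group = g), as.list(count_in(sel))))
  })
  dplyr::bind_rows(rows)
}

#' Apply the data-floor filter
#'
#' Restricts a population to patients carrying at least one ICD10 E28.2
#' (polycystic ovarian syndrome) code event — the minimum-evidence
#' requirement used when drawing the sensitivity/specificity review frame.
#'
#' @param population an [ehr_population()].
#' @param code,icd_version the floor code (default ICD10 "E28.2").
#' @return the filtered [ehr_population()].
#' @export
apply_data_floor <- function(population, code = "E28.2", icd_version = "ICD10") {
  stopifnot(inherits(population, "ehr_population"))
  keep <- unique(population$codes$patient_id[
    population$codes$code == code & population$codes$icd_version == icd_version])
  filter_population(population, keep)
}

#' Subset a population by patient ids
#'
#' @param population an [ehr_population()].
#' @param patient_ids ids to keep.
#' @return the filtered [ehr_population()].
#' @export
filter_population <- function(population, patient_ids) {
  stopifnot(inherits(population, "ehr_population"))
  keep <- population$patients$patient_id %in% patient_ids
  pats <- population$patients[keep, ]
  sub <- function(df) df[df$patient_id %in% pats$patient_id, ]
  ehr_population(
    patients = dplyr::select(pats, -dplyr::any_of("stratum")),
    codes = sub(population$codes),
    notes = sub(population$notes),
    labs = sub(population$labs),
    genetics = if (is.null(population$genetics)) NULL else sub(population$genetics)
  )
}
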