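#' Diagnosis code set
#'
#' A named collection of ICD code patterns. Each member carries the code
#' vocabulary it belongs to (`ICD9` or `ICD10`) so that, e.g., an ICD9
#' "626.x" pattern can never fire on an ICD10 event, and a match mode:
#' `exact` (string equality) or `prefix` (code family, e.g. every 626.x
#' code). Dots are kept in patterns as printed in the vocabularies.
#'
#' @param name code-set name.
#' @param members data frame with columns `pattern`, `icd_version`,
#'   `match_mode`.
#' @return object of class `code_set`.
#' @export
code_set <- function(name, members) {
  members <- tibble::as_tibble(members)
  check_columns(members, c("pattern", "icd_version", "match_mode"), name)
  stopifnot(all(nzchar(members$pattern)),
            all(members$icd_version %in% c("ICD9", "ICD10")),
            all(members$match_mode %in% c("exact", "prefix")))
  if (anyDuplicated(members[, c("pattern", "icd_version")])) {
    stop("duplicate (pattern, icd_version) pair in code set '", name, "'",
         call. = FALSE)
  }
  structure(list(name = name, members = members), class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set>", x$name, "-", nrow(x$members), "member(s)\n")
  print(x$members, n = 10)
  invisible(x)
}

cs_members <- function(pattern, version, mode) {
  tibble::tibble(pattern = pattern, icd_version = version, match_mode = mode)
}

#' Default PCOS code sets
#'
#' The inclusion sets used by the four phenotyping algorithms: polycystic
#' ovaries (ICD9 256.4, ICD10 E28.2), hirsutism (704.1, L68.0) as coded
#' evidence of hyperandrogenism, and irregular menses (the whole ICD9 626
#' family, the whole ICD10 N91 family, plus N92.5 and N92.6). The exclusion
#' set is a synthetic placeholder listing common PCOS mimics (congenital
#' adrenal hyperplasia, Cushing syndrome, androgen-secreting neoplasm,
#' hyperprolactinemia, thyroid dysfunction); real deployments should supply
#' their own exclusion list via [read_algorithm_config()].
#'
#' @return named list of [code_set()] objects.
#' @export
default_code_sets <- function() {
  list(
    polycystic_ovaries = code_set("polycystic_ovaries", rbind(
      cs_members("256.4", "ICD9", "exact"),
      cs_members("E28.2", "ICD10", "exact"))),
    hirsutism = code_set("hirsutism", rbind(
      cs_members("704.1", "ICD9", "exact"),
      cs_members("L68.0", "ICD10", "exact"))),
    irregular_menses = code_set("irregular_menses", rbind(
      cs_members("626", "ICD9", "prefix"),
      cs_members("N91", "ICD10", "prefix"),
      cs_members("N92.5", "ICD10", "exact"),
      cs_members("N92.6", "ICD10", "exact"))),
    pcos_exclusions = code_set("pcos_exclusions", rbind(
      cs_members("255.2", "ICD9", "exact"),   # congenital adrenal hyperplasia
      cs_members("E25",   "ICD10", "prefix"),
      cs_members("255.0", "ICD9", "exact"),   # Cushing syndrome
      cs_members("E24",   "ICD10", "prefix"),
      cs_members("183.0", "ICD9", "exact"),   # ovarian neoplasm (androgen-secreting)
      cs_members("C56",   "ICD10", "prefix"),
      cs_members("253.1", "ICD9", "exact"),   # hyperprolactinemia
      cs_members("E22.1", "ICD10", "exact"),
      cs_members("244.9", "ICD9", "exact"),   # thyroid dysfunction
      cs_members("E03.9", "ICD10", "exact"),
      cs_members("242.9", "ICD9", "exact"),
      cs_members("E05.9", "ICD10", "exact")))
  )
}

# Note types in which a PCOS keyword is allowed to fire, compared after
# case-folding and whitespace normalisation.
DEFAULT_NOTE_TYPES <- c(
  "outpatient note", "gynecology clinic visit", "nursing report",
  "endocrine and diabetes clinic visit", "pediatric endocrinology patient visit",
  "reproductive endocrinology clinic visit"
)

DEFAULT_KEYWORDS <- c("polycystic ovaries", "PCOS", "PCO")

#' Phenotyping algorithm definition
#'
#' Declarative description of one rule-based phenotype: a boolean inclusion
#' expression over code-set names (e.g.
#' `"polycystic_ovaries | (hirsutism & irregular_menses)"`), an exclusion
#' code set, and an optional clinical-note keyword requirement restricted
#' to a whitelist of note types. `inclusion = NA` defines the control rule
#' (no inclusion codes allowed at all).
#'
#' @param name algorithm name.
#' @param inclusion inclusion logic as a string over code-set names using
#'   `&`, `|`, `!` and parentheses, or `NA` for the control rule.
#' @param exclusion name of the exclusion code set.
#' @param keyword_required must a keyword appear in a whitelisted note?
#' @param keywords keyword strings ("PCOS" and "PCO" match as whole
#'   alphanumeric tokens; multi-word keywords as whitespace-normalised
#'   phrases).
#' @param note_types whitelist of note types for keyword search.
#' @param age_range eligible age window in years, inclusive.
#' @return object of class `algorithm_definition`.
#' @export
algorithm_definition <- function(name, inclusion, exclusion = "pcos_exclusions",
                                 keyword_required = FALSE,
                                 keywords = DEFAULT_KEYWORDS,
                                 note_types = DEFAULT_NOTE_TYPES,
                                 age_range = c(11, 44)) {
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  structure(list(name = name, inclusion = inclusion, exclusion = exclusion,
                 keyword_required = isTRUE(keyword_required),
                 keywords = keywords, note_types = note_types,
                 age_range = as.numeric(age_range)),
            class = "algorithm_definition")
}

#' @export
print.algorithm_definition <- function(x, ...) {
  cat("<algorithm_definition>", x$name, "\n")
  cat("  inclusion:", if (is.na(x$inclusion)) "(control: no inclusion codes)"
      else x$inclusion, "\n")
  cat("  exclusion set:", x$exclusion, "\n")
  cat("  keyword required:", x$keyword_required, "\n")
  invisible(x)
}

#' The four nested PCOS algorithms and the control rule
#'
#' From strictest to broadest: `keyword_strict` requires a polycystic-ovaries
#' code OR (hirsutism AND irregular menses), no exclusion code, and a PCOS
#' keyword in a whitelisted note; `coded_strict` drops the keyword
#' requirement; `keyword_broad` requires any one symptom code plus the
#' keyword; `coded_broad` requires any one symptom code. `control` requires
#' no exclusion code and no inclusion code of any kind. By construction the
#' four case sets are nested and controls are disjoint from every case set.
#'
#' @param code_sets named list of [code_set()]s; defaults to
#'   [default_code_sets()].
#' @return object of class `algorithm_set`: list with `code_sets` and
#'   `algorithms`.
#' @export
default_algorithms <- function(code_sets = default_code_sets()) {
  strict <- "polycystic_ovaries | (hirsutism & irregular_menses)"
  broad <- "polycystic_ovaries | hirsutism | irregular_menses"
  algs <- list(
    keyword_strict = algorithm_definition("keyword_strict", strict,
                                          keyword_required = TRUE),
    coded_strict = algorithm_definition("coded_strict", strict),
    keyword_broad = algorithm_definition("keyword_broad", broad,
                                         keyword_required = TRUE),
    coded_broad = algorithm_definition("coded_broad", broad),
    control = algorithm_definition("control", NA_character_)
  )
  algorithm_set(code_sets, algs)
}

#' Bundle code sets with algorithm definitions
#'
#' @param code_sets named list of [code_set()]s.
#' @param algorithms named list of [algorithm_definition()]s.
#' @return object of class `algorithm_set`.
#' @export
algorithm_set <- function(code_sets, algorithms) {
  stopifnot(length(code_sets) > 0, length(algorithms) > 0)
  for (alg in algorithms) {
    validate_inclusion_expr(alg$inclusion, names(code_sets))
    if (!alg$exclusion %in% names(code_sets)) {
      stop("algorithm '", alg$name, "' references unknown exclusion set '",
           alg$exclusion, "'", call. = FALSE)
    }
  }
  structure(list(code_sets = code_sets, algorithms = algorithms),
            class = "algorithm_set")
}

#' @export
print.algorithm_set <- function(x, ...) {
  cat("<algorithm_set>", length(x$algorithms), "algorithm(s),",
      length(x$code_sets), "code set(s)\n")
  for (alg in x$algorithms) {
    cat(" -", alg$name, ":", if (is.na(alg$inclusion)) "(control)" else
      alg$inclusion, if (alg$keyword_required) "+ keyword" else "", "\n")
  }
  invisible(x)
}

# Ensure an inclusion expression only uses known set names and boolean
# operators; returns the parsed expression (or NULL for control rules).
validate_inclusion_expr <- function(expr_string, set_names) {
  if (is.na(expr_string)) return(NULL)
  ex <- tryCatch(str2lang(expr_string),
                 error = function(e) stop("unparseable inclusion expression: ",
                                          expr_string, call. = FALSE))
  used <- all.vars(ex)
  unknown <- setdiff(used, set_names)
  if (length(unknown)) {
    stop("inclusion expression references unknown code set(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ops <- setdiff(all.names(ex), used)
  bad_ops <- setdiff(ops, c("&", "|", "!", "(", "&&", "||"))
  if (length(bad_ops)) {
    stop("inclusion expression uses disallowed operator(s): ",
         paste(bad_ops, collapse = ", "), call. = FALSE)
  }
  ex
}

#' Read an algorithm configuration from YAML
#'
#' The YAML dialect mirrors [default_algorithms()]: a `code_sets` mapping of
#' name to a list of `{pattern, version, mode}` members, and an `algorithms`
#' mapping of name to `{inclusion, exclusion, keyword: {required, keywords,
#' note_types}, age_range}`. See
#' `system.file("extdata", "pcos_algorithms.yaml", package = "pcospectrum")`
#' for the shipped default.
#'
#' @param path YAML file path.
#' @return an [algorithm_set()].
#' @export
read_algorithm_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$code_sets) || is.null(cfg$algorithms)) {
    stop("algorithm config must have 'code_sets' and 'algorithms' blocks",
         call. = FALSE)
  }
  code_sets <- lapply(names(cfg$code_sets), function(nm) {
    members <- dplyr::bind_rows(lapply(cfg$code_sets[[nm]], function(m) {
      tibble::tibble(pattern = m$pattern, icd_version = m$version,
                     match_mode = m$mode %||% "exact")
    }))
    code_set(nm, members)
  })
  names(code_sets) <- names(cfg$code_sets)
  algorithms <- lapply(names(cfg$algorithms), function(nm) {
    a <- cfg$algorithms[[nm]]
    kw <- a$keyword %||% list()
    algorithm_definition(
      name = nm,
      inclusion = if (is.null(a$inclusion)) NA_character_ else a$inclusion,
      exclusion = a$exclusion %||% "pcos_exclusions",
      keyword_required = isTRUE(kw$required),
      keywords = unlist(kw$keywords) %||% DEFAULT_KEYWORDS,
      note_types = unlist(kw$note_types) %||% DEFAULT_NOTE_TYPES,
      age_range = unlist(a$age_range) %||% c(11, 44)
    )
  })
  names(algorithms) <- names(cfg$algorithms)
  algorithm_set(code_sets, algorithms)
}
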