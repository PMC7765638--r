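#' Run the full phenotyping/evaluation/association pipeline
#'
#' Executes the five analysis stages against either a simulated or an
#' on-disk population and writes a plain-text report bundle:
#'
#' 1. **simulate** (or load): build the population and ground truth;
#' 2. **phenotype**: assign the four nested algorithms and the control rule
#'    (`cohorts.tsv`);
#' 3. **evaluate**: chart-review style PPV per algorithm, the 2x2 of the
#'    strictest algorithm against ground truth over the medical-home +
#'    data-floor frame, and EHR prevalences (`metrics.json`,
#'    `table2_prevalence.tsv`, `table3_confusion.json`);
#' 4. **labs**: clean, trim, summarise and age-adjust lab values
#'    (`labs_clean.tsv`, `labs_adjusted.tsv`, `table4_labs.tsv`);
#' 5. **assoc**: matched logistic PRS models per algorithm and ancestry
#'    (`table5_assoc.tsv`).
#'
#' Also emits `table1_demographics.tsv` and `provenance.json` (package
#' version, seed, config hash). All randomness flows from the single root
#' `seed` via named substreams, so a config + seed pair yields a
#' byte-identical bundle. Any stage failure aborts with the stage name;
#' artifacts already written are preserved.
#'
#' @param config a [sim_config()] (the simulated study conditions), or a
#'   directory path containing population tables for [read_population()]
#'   (in which case evaluation against ground truth is skipped unless
#'   `truth` is supplied).
#' @param seed integer root seed.
#' @param out_dir output directory for the report bundle.
#' @param algorithms an [algorithm_set()].
#' @param n_review charts per algorithm for the PPV review sample.
#' @param match_ratio controls per case for the association matching.
#' @param truth optional ground-truth table when `config` is a directory.
#' @return (invisibly) a list with the in-memory stage results:
#'   `population`, `truth`, `cohorts`, `metrics`, `lab_summary`,
#'   `adjusted_labs`, `assoc`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir,
                         algorithms = default_algorithms(), n_review = 50,
                         match_ratio = 4, truth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate / load -----------------------------------------------------
  sim <- stage("simulate", {
    if (inherits(config, "sim_config")) {
      generate_population(config, seed)
    } else {
      list(population = read_population(config), truth = truth)
    }
  })
  population <- sim$population
  truth <- sim$truth
  if (!is.null(truth)) write_truth(truth, file.path(out_dir, "truth.tsv"))

  # -- phenotype -----------------------------------------------------------
  cohorts <- stage("phenotype", build_cohorts(population, algorithms))
  readr::write_tsv(cohorts, file.path(out_dir, "cohorts.tsv"))
  summary_tab <- cohort_summary(cohorts)
  algs <- attr(cohorts, "case_algorithms")

  # -- demographics (Table 1 layout) ---------------------------------------
  feats <- patient_features(population)
  demo <- stage("report_demographics", {
    rows <- lapply(c(algs, "control"), function(a) {
      sel <- cohorts[[a]]
      ids <- cohorts$patient_id[!is.na(sel) & sel]
      f <- feats[feats$patient_id %in% ids, ]
      tibble::tibble(
        algorithm = a, n = nrow(f),
        mean_age = mean(f$age_at_last_code),
        sd_age = stats::sd(f$age_at_last_code),
        mean_record_length = mean(f$record_length_years, na.rm = TRUE),
        sd_record_length = stats::sd(f$record_length_years, na.rm = TRUE),
        medical_home_pct = pct_int(mean(f$medical_home))
      )
    })
    dplyr::bind_rows(rows)
  })
  readr::write_tsv(demo, file.path(out_dir, "table1_demographics.tsv"))

  # -- evaluate ------------------------------------------------------------
  metrics <- stage("evaluate", {
    n_eligible <- sum(cohorts$eligible, na.rm = TRUE)
    prev <- lapply(algs, function(a) {
      n_cases <- sum(cohorts[[a]], na.rm = TRUE)
      c(list(algorithm = a), prevalence(n_cases, n_eligible)[
        c("n_cases", "n_population", "prevalence_pct", "rendered")])
    })
    prev_tab <- dplyr::bind_rows(lapply(prev, tibble::as_tibble_row))

    ppv_tab <- NULL
    confusion <- NULL
    if (!is.null(truth)) {
      review <- generate_chart_review_sample(truth, cohorts, algs,
                                             n = min(n_review,
                                                     min(prev_tab$n_cases)),
                                             seed = seed)
      ppv_tab <- review |>
        dplyr::group_by(.data$algorithm) |>
        dplyr::summarise(n_reviewed = dplyr::n(),
                         n_true_positive = sum(.data$true_case),
                         .groups = "drop") |>
        dplyr::mutate(ppv_pct = pct_int(.data$n_true_positive / .data$n_reviewed))

      frame_ids <- intersect(
        feats$patient_id[feats$medical_home],
        apply_data_floor(population)$patients$patient_id)
      frame_ids <- intersect(frame_ids,
                             cohorts$patient_id[cohorts$eligible])
      if (length(frame_ids)) {
        cc <- evaluate_against_truth(cohorts, truth, "keyword_strict",
                                     frame_ids = frame_ids)
        confusion <- c(unclass(cc),
                       lapply(confusion_metrics(cc)$percent, as.integer))
      }
    }
    list(prevalence = prev_tab, ppv = ppv_tab, confusion = confusion)
  })
  readr::write_tsv(metrics$prevalence, file.path(out_dir, "table2_prevalence.tsv"))
  if (!is.null(metrics$ppv)) {
    readr::write_tsv(metrics$ppv, file.path(out_dir, "table2_ppv.tsv"))
  }
  jsonlite::write_json(metrics[c("confusion")],
                       file.path(out_dir, "table3_confusion.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # -- labs ----------------------------------------------------------------
  labres <- stage("labs", {
    raw <- derive_bmi(population$labs)
    clean <- clean_lab_table(raw, population$patients)
    trimmed <- suppressWarnings(trim_percentile_outliers(clean))
    summary_tab4 <- summarize_labs_by_group(trimmed, cohorts)
    adjusted <- suppressWarnings(age_adjust_inverse_normal(trimmed))
    list(clean = clean, trimmed = trimmed, summary = summary_tab4,
         adjusted = adjusted)
  })
  readr::write_tsv(labres$trimmed, file.path(out_dir, "labs_clean.tsv"))
  readr::write_tsv(labres$adjusted, file.path(out_dir, "labs_adjusted.tsv"))
  readr::write_tsv(labres$summary, file.path(out_dir, "table4_labs.tsv"))

  # -- assoc ---------------------------------------------------------------
  assoc <- stage("assoc", {
    if (is.null(population$genetics)) return(NULL)
    gene <- dplyr::inner_join(population$genetics,
                              cohorts[, c("patient_id", "age", "stratum",
                                          "eligible", algs, "control")],
                              by = "patient_id")
    gene <- gene[gene$eligible & gene$patient_id %in%
                   feats$patient_id[feats$medical_home], ]
    rows <- list()
    for (anc in c("EUR", "AFR")) {
      sub <- gene[gene$ancestry == anc, ]
      for (a in algs) {
        df <- sub[!is.na(sub[[a]]) & (sub[[a]] | sub$control), ]
        df$case <- df[[a]]
        matched <- tryCatch(
          suppressWarnings(match_cases_controls(df, ratio = match_ratio,
                                                seed = derive_seed(seed, paste0(anc, a)))),
          error = function(e) NULL)
        if (is.null(matched) || !nrow(matched)) next
        mdat <- dplyr::left_join(
          matched[, c("patient_id", "case")],
          gene[, c("patient_id", "prs", paste0("pc", 1:10), "age")],
          by = "patient_id")
        names(mdat)[names(mdat) == "age"] <- "median_age"
        res <- tryCatch(
          logistic_prs_assoc(mdat, covariates = c("median_age", paste0("pc", 1:10)),
                             label = paste(anc, a)),
          error = function(e) NULL)
        if (is.null(res)) next
        rows[[paste(anc, a)]] <- tibble::tibble(
          ancestry = anc, algorithm = a,
          n_cases = res$n_cases, n_controls = res$n_controls,
          estimate = res$beta, se = res$se, p = res$p, or = res$or,
          lci = res$ci95[1], uci = res$ci95[2], prs_r2 = res$pseudo_r2)
      }
    }
    dplyr::bind_rows(rows)
  })
  if (!is.null(assoc) && nrow(assoc)) {
    readr::write_tsv(assoc, file.path(out_dir, "table5_assoc.tsv"))
  }

  # -- provenance ----------------------------------------------------------
  prov <- list(
    package = "pcospectrum",
    version = as.character(utils::packageVersion("pcospectrum")),
    seed = seed,
    config_hash = rlang::hash(config),
    n_patients = nrow(population$patients)
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(population = population, truth = truth, cohorts = cohorts,
                 summary = summary_tab, metrics = metrics,
                 lab_summary = labres$summary, adjusted_labs = labres$adjusted,
                 assoc = assoc, provenance = prov))
}
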