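raw_lab_row <- function(id, analyte, value, unit = "mcU/mL", date = "2014-01-01") {
  tibble::tibble(patient_id = id, analyte = analyte, value = as.character(value),
                 unit = unit, date = as.Date(date))
}

test_that("cleaning drops non-numeric values before the per-patient median", {
  raw <- dplyr::bind_rows(
    raw_lab_row("a", "insulin", "5.1"),
    raw_lab_row("a", "insulin", "QNS", date = "2014-02-01"),
    raw_lab_row("a", "insulin", "5.3", date = "2014-03-01"),
    raw_lab_row("b", "insulin", "7.0")
  )
  clean <- clean_lab_table(raw)
  expect_equal(clean$median_value[clean$patient_id == "a"], 5.2)
  expect_identical(attr(clean, "drop_log")[["nonnumeric"]], 1L)
})

test_that("analytes observed in a single patient are removed", {
  raw <- dplyr::bind_rows(
    raw_lab_row("a", "rare_assay", "1.0"),
    raw_lab_row("a", "rare_assay", "2.0", date = "2014-02-01"),
    raw_lab_row("a", "insulin", "5.0"),
    raw_lab_row("b", "insulin", "6.0")
  )
  clean <- clean_lab_table(raw)
  expect_false("rare_assay" %in% clean$analyte)
  expect_identical(attr(clean, "drop_log")[["single_patient_analyte"]], 2L)
})

test_that("duplicates and discordant units are filtered", {
  raw <- dplyr::bind_rows(
    raw_lab_row("a", "insulin", "5.0"),
    raw_lab_row("a", "insulin", "5.0"),          # exact duplicate
    raw_lab_row(sprintf("c%02d", 1:9), "insulin", "8.0"),
    raw_lab_row("d", "insulin", "55.0", unit = "pmol/L")  # discordant unit
  )
  clean <- clean_lab_table(raw)
  log <- attr(clean, "drop_log")
  expect_identical(log[["duplicate"]], 1L)
  expect_identical(log[["discordant_unit"]], 1L)
  expect_false("d" %in% clean$patient_id)
  expect_true(all(clean$unit == "mcU/mL"))
})

test_that("cleaning is idempotent on already-clean data", {
  sim <- small_sim(n = 1000, seed = 17)
  clean <- clean_lab_table(sim$population$labs)
  again <- clean_lab_table(tibble::tibble(
    patient_id = clean$patient_id, analyte = clean$analyte,
    value = as.character(clean$median_value), unit = clean$unit,
    date = as.Date("2014-01-01")))
  expect_equal(again$median_value, clean$median_value)
  expect_identical(sum(attr(again, "drop_log")), 0L)
})

test_that("cleaning output is invariant to input row order", {
  sim <- small_sim(n = 500, seed = 23)
  labs <- sim$population$labs
  set.seed(1)
  shuffled <- labs[sample(nrow(labs)), ]
  c1 <- clean_lab_table(labs, sim$population$patients)
  c2 <- clean_lab_table(shuffled, sim$population$patients)
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("percentile trimming removes strict outliers by interpolation", {
  series <- tibble::tibble(analyte = "x", median_value = as.numeric(1:100))
  trimmed <- trim_percentile_outliers(series)
  # p1 = 1.99 and p99 = 99.01 under linear interpolation
  expect_setequal(setdiff(series$median_value, trimmed$median_value), c(1, 100))
  expect_identical(attr(trimmed, "n_trimmed")[["x"]], 2L)
  # identical values: nothing removed
  same <- tibble::tibble(analyte = "x", median_value = rep(5, 50))
  expect_identical(nrow(trim_percentile_outliers(same)), 50L)
  # below the guard size the series is returned unchanged with a warning
  tiny <- tibble::tibble(analyte = "x", median_value = c(1, 2, 3, 4, 1000))
  expect_warning(out <- trim_percentile_outliers(tiny), "fewer than")
  expect_identical(nrow(out), 5L)
})

test_that("trimming removes at most about two percent of continuous data", {
  set.seed(7)
  series <- tibble::tibble(analyte = "x", median_value = rlnorm(5000))
  trimmed <- trim_percentile_outliers(series)
  removed <- nrow(series) - nrow(trimmed)
  expect_lte(removed / nrow(series), 0.021)
})

test_that("the inverse normal transform is standard normal and monotone", {
  set.seed(42)
  x <- rgamma(500, 2)
  z <- inverse_normal_transform(x)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_identical(order(x), order(z))
  # Blom symmetry: the middle of three distinct values maps to exactly 0
  expect_equal(inverse_normal_transform(c(10, -3, 5))[3], 0)
})

test_that("age adjustment decorrelates the transformed value from age", {
  set.seed(5)
  n <- 1000
  ages <- runif(n, 15, 44)
  series <- tibble::tibble(
    patient_id = sprintf("s%04d", 1:n), analyte = "insulin",
    median_value = 2 + 0.4 * ages + rnorm(n), median_age = ages)
  adj <- age_adjust_inverse_normal(series)
  expect_identical(nrow(adj), as.integer(n))
  expect_lt(abs(cor(adj$z, ages)), 0.05)
  expect_lt(abs(mean(adj$z)), 0.02)
  expect_lt(abs(sd(adj$z) - 1), 0.05)
  # zero age variance: regression skipped with a warning, values transformed
  flat <- dplyr::mutate(series, median_age = 30)
  expect_warning(adj2 <- age_adjust_inverse_normal(flat), "zero age variance")
  expect_identical(order(adj2$z), order(flat$median_value))
  # too few observations: analyte skipped with a warning
  expect_warning(out <- age_adjust_inverse_normal(series[1:5, ]), "fewer than")
  expect_identical(nrow(out), 0L)
})

test_that("group summaries report median and quartiles per algorithm", {
  sim <- small_sim(n = 4000, seed = 29)
  coh <- build_cohorts(sim$population)
  clean <- clean_lab_table(derive_bmi(sim$population$labs),
                           sim$population$patients)
  s <- summarize_labs_by_group(clean, coh)
  bmi <- s[s$analyte == "bmi", ]
  expect_true(all(c("Cases", "Controls") %in% bmi$group))
  expect_true(all(bmi$q25 <= bmi$median & bmi$median <= bmi$q75))
  ks <- bmi$median[bmi$algorithm == "keyword_strict" & bmi$group == "Cases"]
  cb <- bmi$median[bmi$algorithm == "coded_broad" & bmi$group == "Cases"]
  ctl <- bmi$median[bmi$algorithm == "coded_broad" & bmi$group == "Controls"]
  expect_gte(ks, cb)
  expect_gt(cb, ctl)
  # a single-value group collapses median and quartiles onto that value
  one <- summarize_labs_by_group(
    tibble::tibble(patient_id = coh$patient_id[which(coh$keyword_strict)[1]],
                   analyte = "bmi", median_value = 33),
    coh)
  row <- one[one$algorithm == "keyword_strict" & one$group == "Cases", ]
  expect_equal(row$median, 33)
  expect_equal(row$q25, 33)
  expect_equal(row$q75, 33)
})

test_that("BMI is derived from same-day weight/height pairs", {
  raw <- dplyr::bind_rows(
    raw_lab_row("a", "weight", "81.0", unit = "kg"),
    raw_lab_row("a", "height", "1.80", unit = "m"),
    raw_lab_row("b", "bmi", "30.0", unit = "kg/m2"),
    raw_lab_row("c", "weight", "70.0", unit = "kg"),
    raw_lab_row("c", "height", "0.9", unit = "m")  # implausible height
  )
  out <- derive_bmi(raw)
  a <- out[out$patient_id == "a" & out$analyte == "bmi", ]
  expect_equal(as.numeric(a$value), 25, tolerance = 1e-6)
  expect_false("weight" %in% out$analyte)
  expect_false("c" %in% out$patient_id[out$analyte == "bmi"])
  expect_true("b" %in% out$patient_id[out$analyte == "bmi"])
})
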