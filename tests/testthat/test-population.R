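test_that("age_at computes years with the 365.25-day convention", {
  expect_equal(age_at(as.Date("2000-01-01"), as.Date("2011-01-01")), 11,
               tolerance = 0.01)
  expect_equal(age_at(as.Date("2000-01-01"), as.Date("2000-01-01")), 0)
  expect_equal(age_at(as.Date("1990-06-15"), as.Date("2020-06-15")), 30,
               tolerance = 0.01)
  expect_error(age_at(as.Date("2000-01-01"), as.Date("1999-12-31")),
               "precedes")
})

test_that("record length spans first to last code event", {
  pop <- make_test_population()
  rl <- record_length_years(pop)
  # p4: codes 2013-01-01 and 2014-01-01 -> 1 year
  expect_equal(rl$record_length_years[rl$patient_id == "p4"], 1,
               tolerance = 0.01)
  # p2: a single code event -> 0
  expect_equal(rl$record_length_years[rl$patient_id == "p2"], 0)
  # a patient with no code events gets an explicit missing marker
  pats <- tibble::tibble(patient_id = "q1", birth_date = as.Date("1990-01-01"),
                         sex = "F", race = "White", hispanic = FALSE)
  empty <- tibble::tibble(patient_id = character(), code = character(),
                          icd_version = character(), date = as.Date(character()))
  notes <- tibble::tibble(patient_id = character(), note_type = character(),
                          date = as.Date(character()), text = character())
  labs <- tibble::tibble(patient_id = character(), analyte = character(),
                         value = character(), unit = character(),
                         date = as.Date(character()))
  pop0 <- ehr_population(pats, empty, notes, labs)
  expect_true(is.na(record_length_years(pop0)$record_length_years))
})

make_codes_pop <- function(dates) {
  pats <- tibble::tibble(patient_id = "x", birth_date = as.Date("1980-01-01"),
                         sex = "F", race = "White", hispanic = FALSE)
  codes <- tibble::tibble(patient_id = "x", code = "J06.9",
                          icd_version = "ICD10", date = as.Date(dates))
  notes <- tibble::tibble(patient_id = character(), note_type = character(),
                          date = as.Date(character()), text = character())
  labs <- tibble::tibble(patient_id = character(), analyte = character(),
                         value = character(), unit = character(),
                         date = as.Date(character()))
  ehr_population(pats, codes, notes, labs)
}

test_that("medical home needs five distinct days over three-plus years", {
  # 5 distinct days spanning 3.1 years
  days <- as.Date("2010-01-01") + c(0, 300, 600, 900, round(3.1 * 365.25))
  expect_true(is_medical_home(make_codes_pop(days))$medical_home)
  # 5 codes all on one day
  expect_false(is_medical_home(make_codes_pop(rep("2010-01-01", 5)))$medical_home)
  # 4 distinct days spanning 10 years
  days4 <- as.Date("2010-01-01") + c(0, 1000, 2000, 3653)
  expect_false(is_medical_home(make_codes_pop(days4))$medical_home)
})

test_that("medical home is monotone under added code events", {
  set.seed(401)
  for (i in 1:20) {
    base_days <- as.Date("2009-06-01") + sample(0:2000, sample(3:8, 1))
    before <- is_medical_home(make_codes_pop(base_days))$medical_home
    extra <- as.Date("2009-06-01") + sample(0:2000, 3)
    after <- is_medical_home(make_codes_pop(c(base_days, extra)))$medical_home
    if (before) expect_true(after)
  }
})

test_that("date-derived features are translation invariant", {
  pop <- make_test_population()
  shift <- 1234L
  shifted <- ehr_population(
    dplyr::mutate(dplyr::select(pop$patients, -stratum),
                  birth_date = birth_date + shift),
    dplyr::mutate(pop$codes, date = date + shift),
    dplyr::mutate(pop$notes, date = date + shift),
    dplyr::mutate(pop$labs, date = date + shift)
  )
  f1 <- patient_features(pop)
  f2 <- patient_features(shifted)
  expect_equal(f1$record_length_years, f2$record_length_years, tolerance = 0.01)
  expect_equal(f1$age_at_last_code, f2$age_at_last_code, tolerance = 0.01)
  expect_identical(f1$medical_home, f2$medical_home)
})

test_that("populations round-trip through the TSV writer and reader", {
  sim <- small_sim(n = 200, seed = 5)
  dir <- withr::local_tempdir()
  write_population(sim$population, dir)
  back <- read_population(dir, quiet = TRUE)
  expect_equal(back$patients, sim$population$patients)
  expect_equal(back$codes, sim$population$codes)
  expect_equal(back$notes, sim$population$notes)
  expect_equal(back$labs, sim$population$labs)
  expect_equal(back$genetics, sim$population$genetics)
  expect_identical(sum(attr(back, "rejections")), 0L)
})

test_that("reader drops and counts invalid rows, errors on missing columns", {
  pop <- make_test_population()
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  # inject a code event dated before birth
  codes <- readr::read_tsv(file.path(dir, "codes.tsv"), show_col_types = FALSE)
  codes <- rbind(codes, data.frame(patient_id = "p1", code = "J06.9",
                                   icd_version = "ICD10",
                                   date = as.Date("1980-01-01")))
  readr::write_tsv(codes, file.path(dir, "codes.tsv"))
  back <- read_population(dir, quiet = TRUE)
  expect_identical(attr(back, "rejections")[["codes"]], 1L)
  expect_equal(nrow(back$codes), nrow(pop$codes))

  # missing mandatory column is a hard error naming it
  bad <- codes[, setdiff(names(codes), "icd_version")]
  readr::write_tsv(bad, file.path(dir, "codes.tsv"))
  expect_error(read_population(dir, quiet = TRUE), "icd_version")
})

test_that("empty files load as an empty population without error", {
  dir <- withr::local_tempdir()
  file.create(file.path(dir, "patients.tsv"))
  pop <- read_population(dir, quiet = TRUE)
  expect_s3_class(pop, "ehr_population")
  expect_identical(nrow(pop$patients), 0L)
  expect_identical(nrow(pop$codes), 0L)
})

test_that("hispanic ethnicity overrides race in stratum resolution", {
  expect_identical(
    resolve_stratum(c("White", "AfricanAmerican", "White", "AfricanAmerican", NA),
                    c(FALSE, FALSE, TRUE, TRUE, FALSE)),
    c("NH White", "NH African American", "Hispanic", "Hispanic", "Other"))
})

test_that("constructor enforces container invariants", {
  pop <- make_test_population()
  dup <- rbind(pop$patients[1, ], pop$patients[1, ])
  expect_error(ehr_population(dup[, 1:5], pop$codes[0, ], pop$notes[0, ],
                              pop$labs[0, ]), "duplicate")
  orphan <- pop$codes
  orphan$patient_id[1] <- "ghost"
  expect_error(ehr_population(dplyr::select(pop$patients, -stratum), orphan,
                              pop$notes, pop$labs), "absent")
})
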