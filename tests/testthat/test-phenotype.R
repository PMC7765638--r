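test_that("code-set matching respects version, exact and prefix modes", {
  pop <- make_test_population()
  cs <- default_code_sets()
  pco <- matches_code_set(pop, cs$polycystic_ovaries)
  expect_true(pco$matched[pco$patient_id == "p1"])   # E28.2 ICD10
  expect_false(pco$matched[pco$patient_id == "p2"])
  irr <- matches_code_set(pop, cs$irregular_menses)
  expect_true(irr$matched[irr$patient_id == "p2"])   # 626.4 under the 626 family
  expect_true(irr$matched[irr$patient_id == "p7"])   # N92.5 exact
  # N92.4 is not in {N91*, N92.5, N92.6}
  pats <- tibble::tibble(patient_id = "x", birth_date = as.Date("1990-01-01"),
                         sex = "F", race = "White", hispanic = FALSE)
  codes <- tibble::tibble(patient_id = "x", code = "N92.4",
                          icd_version = "ICD10", date = as.Date("2014-01-01"))
  px <- ehr_population(pats, codes, pop$notes[0, ], pop$labs[0, ])
  expect_false(matches_code_set(px, cs$irregular_menses)$matched)
  # an ICD9-looking string under the wrong version never fires
  codes9 <- tibble::tibble(patient_id = "x", code = "626.4",
                           icd_version = "ICD10", date = as.Date("2014-01-01"))
  p9 <- ehr_population(pats, codes9, pop$notes[0, ], pop$labs[0, ])
  expect_false(matches_code_set(p9, cs$irregular_menses)$matched)
})

test_that("keyword matching is token-based, case-folded and whitelisted", {
  pop <- make_test_population()
  kw <- has_keyword(pop)
  hit <- function(id) kw$has_keyword[kw$patient_id == id]
  expect_true(hit("p1"))    # "PCOS," in an outpatient note
  expect_true(hit("p7"))    # phrase with irregular spacing, case-folded type
  expect_false(hit("p8"))   # "pcostatin" must not fire "PCO"
  expect_false(hit("p4"))   # radiology report is not whitelisted
  # substring mode is available behind the flag and does fire on pcostatin
  kw_sub <- has_keyword(pop, mode = "substring")
  expect_true(kw_sub$has_keyword[kw_sub$patient_id == "p8"])
})

test_that("classification reproduces the nested algorithm logic", {
  pop <- make_test_population()
  coh <- build_cohorts(pop)
  row <- function(id) coh[coh$patient_id == id, ]
  algs <- c("keyword_strict", "coded_strict", "keyword_broad", "coded_broad")
  # E28.2 + whitelisted keyword note -> case under all four
  expect_true(all(unlist(row("p1")[algs])))
  # only an irregular-menses code -> coded_broad only
  expect_identical(unlist(row("p2")[algs]),
                   c(keyword_strict = FALSE, coded_strict = FALSE,
                     keyword_broad = FALSE, coded_broad = TRUE))
  # any exclusion code removes the patient from every case set and controls
  expect_false(any(unlist(row("p3")[c(algs, "control")])))
  # hirsutism AND irregular menses + phrase note -> strict combination fires
  expect_true(all(unlist(row("p7")[algs])))
  # pcostatin distractor: coded algorithms only
  expect_identical(unlist(row("p8")[algs]),
                   c(keyword_strict = FALSE, coded_strict = TRUE,
                     keyword_broad = FALSE, coded_broad = TRUE))
  # filler-only patient is a control
  expect_true(row("p4")$control)
  expect_false(any(unlist(row("p4")[algs])))
  # ineligible patients carry NA labels and classify_patient refuses them
  expect_true(is.na(row("p5")$coded_broad))
  expect_true(is.na(row("p6")$coded_broad))
  expect_error(classify_patient(pop, "p5", "coded_broad"), "ineligible")
  expect_identical(classify_patient(pop, "p1", "keyword_strict"), "case")
  expect_identical(classify_patient(pop, "p2", "keyword_strict"), "not_case")
})

test_that("case sets are nested and controls disjoint on simulated data", {
  for (seed in 1:3) {
    sim <- small_sim(n = 3000, seed = seed)
    coh <- build_cohorts(sim$population)
    ks <- which(coh$keyword_strict); cs <- which(coh$coded_strict)
    kb <- which(coh$keyword_broad); cb <- which(coh$coded_broad)
    expect_true(all(ks %in% cs))
    expect_true(all(ks %in% kb))
    expect_true(all(cs %in% cb))
    expect_true(all(kb %in% cb))
    ctl <- which(coh$control)
    expect_length(intersect(ctl, union(cb, union(cs, union(kb, ks)))), 0)
  }
})

test_that("cohort labels agree with a brute-force recount from ground truth", {
  sim <- small_sim(n = 4000, seed = 9)
  coh <- build_cohorts(sim$population)
  truth <- sim$truth
  df <- dplyr::inner_join(coh, truth, by = "patient_id")
  el <- df$eligible
  strict_incl <- df$pco_code | (df$hirsutism_code & df$irregular_menses_code)
  broad_incl <- df$pco_code | df$hirsutism_code | df$irregular_menses_code
  expect_identical(df$keyword_strict[el],
                   (strict_incl & !df$exclusion_code & df$keyword_documented)[el])
  expect_identical(df$coded_strict[el], (strict_incl & !df$exclusion_code)[el])
  expect_identical(df$keyword_broad[el],
                   (broad_incl & !df$exclusion_code & df$keyword_documented)[el])
  expect_identical(df$coded_broad[el], (broad_incl & !df$exclusion_code)[el])
  expect_identical(df$control[el], (!broad_incl & !df$exclusion_code)[el])
})

test_that("classification is invariant to event order and duplicates", {
  pop <- make_test_population()
  coh1 <- build_cohorts(pop)
  shuffled <- pop
  set.seed(2)
  perm <- sample(nrow(pop$codes))
  pop2 <- ehr_population(dplyr::select(pop$patients, -stratum),
                         rbind(pop$codes[perm, ], pop$codes[1:3, ]),
                         pop$notes, pop$labs)
  coh2 <- build_cohorts(pop2)
  expect_equal(as.data.frame(coh1), as.data.frame(coh2))
})

test_that("keyword requirement and exclusions act monotonically", {
  sim <- small_sim(n = 2000, seed = 4)
  coh <- build_cohorts(sim$population)
  # dropping the keyword requirement can only grow a case set
  expect_true(all(which(coh$keyword_strict) %in% which(coh$coded_strict)))
  expect_true(all(which(coh$keyword_broad) %in% which(coh$coded_broad)))
  # stamping an exclusion code on every patient empties cases and controls
  pop <- sim$population
  excl <- tibble::tibble(patient_id = pop$patients$patient_id, code = "255.2",
                         icd_version = "ICD9",
                         date = pop$patients$birth_date + 6000)
  pop2 <- ehr_population(dplyr::select(pop$patients, -stratum),
                         rbind(pop$codes, excl), pop$notes, pop$labs,
                         pop$genetics)
  coh2 <- build_cohorts(pop2)
  for (a in c("keyword_strict", "coded_strict", "keyword_broad", "coded_broad",
              "control")) {
    expect_identical(sum(coh2[[a]], na.rm = TRUE), 0L)
  }
})

test_that("a population with no eligible females yields empty cohorts", {
  pop <- make_test_population()
  males <- dplyr::mutate(dplyr::select(pop$patients, -stratum), sex = "other")
  pop2 <- ehr_population(males, pop$codes, pop$notes, pop$labs)
  coh <- build_cohorts(pop2)
  expect_identical(sum(coh$eligible), 0L)
  expect_identical(sum(coh$coded_broad, na.rm = TRUE), 0L)
  expect_identical(sum(coh$control, na.rm = TRUE), 0L)
})

test_that("data floor keeps only carriers of ICD10 E28.2", {
  pop <- make_test_population()
  floored <- apply_data_floor(pop)
  expect_setequal(floored$patients$patient_id,
                  c("p1", "p3", "p5", "p6", "p8"))
  # an ICD9 256.4 carrier alone does not meet the floor
  pats <- tibble::tibble(patient_id = "x", birth_date = as.Date("1990-01-01"),
                         sex = "F", race = "White", hispanic = FALSE)
  codes <- tibble::tibble(patient_id = "x", code = "256.4",
                          icd_version = "ICD9", date = as.Date("2014-01-01"))
  px <- ehr_population(pats, codes, pop$notes[0, ], pop$labs[0, ])
  expect_identical(nrow(apply_data_floor(px)$patients), 0L)
  # empty population stays empty
  p0 <- filter_population(pop, character(0))
  expect_identical(nrow(apply_data_floor(p0)$patients), 0L)
})

test_that("the YAML algorithm config round-trips the default definitions", {
  path <- system.file("extdata", "pcos_algorithms.yaml", package = "pcospectrum")
  cfg <- read_algorithm_config(path)
  pop <- make_test_population()
  coh_default <- build_cohorts(pop)
  coh_yaml <- build_cohorts(pop, cfg)
  expect_equal(as.data.frame(coh_default), as.data.frame(coh_yaml))
})

test_that("algorithm validation rejects malformed definitions", {
  cs <- default_code_sets()
  expect_error(algorithm_set(cs, list(algorithm_definition("bad", "nonexistent_set"))),
               "unknown code set")
  expect_error(algorithm_set(cs, list(
    algorithm_definition("bad", "polycystic_ovaries + hirsutism"))),
    "disallowed operator")
  expect_error(code_set("dup", data.frame(
    pattern = c("626", "626"), icd_version = c("ICD9", "ICD9"),
    match_mode = c("prefix", "prefix"))), "duplicate")
})
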