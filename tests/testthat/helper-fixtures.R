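# Hand-built miniature population with known phenotype outcomes.
#
# p1: E28.2 + whitelisted "PCOS" note            -> case under all four
# p2: only an irregular-menses code (626.4)      -> coded_broad only
# p3: E28.2 + exclusion code                     -> not a case anywhere
# p4: filler codes only                          -> control
# p5: male with E28.2                            -> ineligible
# p6: out of age range                           -> ineligible
# p7: hirsutism + irregular menses + phrase note -> case under all four
# p8: E28.2 + "pcostatin" distractor note        -> coded algorithms only
make_test_population <- function() {
  d <- as.Date
  patients <- tibble::tibble(
    patient_id = paste0("p", 1:8),
    birth_date = d(c("1990-01-01", "1995-01-01", "1992-01-01", "1988-01-01",
                     "1991-01-01", "1960-01-01", "1993-01-01", "1994-01-01")),
    sex = c("F", "F", "F", "F", "other", "F", "F", "F"),
    race = c("White", "AfricanAmerican", "White", "White", "White", "White",
             "White", "Other"),
    hispanic = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  codes <- tibble::tibble(
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p4", "p4", "p5", "p6",
                   "p7", "p7", "p7", "p8", "p8"),
    code = c("E28.2", "J06.9", "626.4", "E28.2", "255.2", "J06.9", "465.9",
             "E28.2", "E28.2", "704.1", "N92.5", "J06.9", "E28.2", "R05"),
    icd_version = c("ICD10", "ICD10", "ICD9", "ICD10", "ICD9", "ICD10",
                    "ICD9", "ICD10", "ICD10", "ICD9", "ICD10", "ICD10",
                    "ICD10", "ICD10"),
    date = d(c("2014-01-01", "2014-06-01", "2014-03-01", "2014-01-01",
               "2014-02-01", "2013-01-01", "2014-01-01", "2014-01-01",
               "2014-01-01", "2014-01-01", "2014-05-01", "2014-06-01",
               "2014-01-01", "2014-04-01"))
  )
  notes <- tibble::tibble(
    patient_id = c("p1", "p7", "p8", "p4"),
    note_type = c("outpatient note", "Gynecology  Clinic Visit",
                  "outpatient note", "radiology report"),
    date = d(c("2014-02-01", "2014-05-15", "2014-02-01", "2014-01-15")),
    text = c("Assessment: PCOS, obesity. Plan discussed.",
             "polycystic   ovaries seen on US today.",
             "pcostatin prescribed for lipids.",
             "PCOS suspected on imaging.")
  )
  labs <- tibble::tibble(
    patient_id = c("p1", "p1", "p2"),
    analyte = c("bmi", "bmi", "bmi"),
    value = c("31.2", "33.0", "22.5"),
    unit = "kg/m2",
    date = d(c("2014-01-01", "2014-06-01", "2014-03-01"))
  )
  ehr_population(patients, codes, notes, labs)
}

# Independent brute-force two-sided exact p for the rank-sum test:
# enumerate every assignment of the pooled ranks to group x.
enumerate_rank_sum_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U for x
  combs <- utils::combn(length(pooled), nx)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  p_low <- mean(u_all <= w_obs)
  p_high <- mean(u_all >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Quick population from the generator with small n for property tests.
small_sim <- function(n = 2000, seed = 1, ...) {
  generate_population(sim_config(n_patients = n, ...), seed = seed)
}
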