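test_that("the index date is the first qualifying antidepressant dispensing", {
  w <- as.Date(c("2013-01-01", "2014-09-30"))
  ph <- rbind(ph_fix(28L), ph_fix(0L))          # 2013-03-01 and 2013-02-01
  expect_identical(find_index_date(ph, w), ORIGIN)
  # non-antidepressant dispensings never qualify
  ph2 <- ph_fix(0L, drug = "quetiapine", class = "antipsychotic")
  expect_true(is.na(find_index_date(ph2, w)))
  # dispensing before the window start does not qualify
  ph3 <- ph_fix(0L, origin = as.Date("2012-11-01"))
  expect_true(is.na(find_index_date(ph3, w)))
})

test_that("a textbook-eligible patient passes every criterion", {
  f <- eligible_fixture()
  r <- check_eligibility(f$patient, f$pharmacy, f$medical, f$enrollment,
                         f$index)
  expect_true(r$eligible)
  expect_length(r$reasons, 0)
})

test_that("the diagnosis must fall within 30 days of the index date", {
  for (off in c(-31L, 31L)) {
    f <- eligible_fixture(dx_day = off)
    r <- check_eligibility(f$patient, f$pharmacy, f$medical, f$enrollment,
                           f$index)
    expect_false(r$eligible)
    expect_identical(r$reasons, "diagnosis_window")
  }
  for (off in c(-30L, 0L, 30L)) {
    f <- eligible_fixture(dx_day = off)
    expect_true(check_eligibility(f$patient, f$pharmacy, f$medical,
                                  f$enrollment, f$index)$eligible)
  }
})

test_that("the pre-index washout is 183 days and catches any depression treatment", {
  f <- eligible_fixture()
  # antidepressant fill 100 days before index
  ph <- rbind(f$pharmacy, ph_fix(-100L))
  r <- check_eligibility(f$patient, ph, f$medical, f$enrollment, f$index)
  expect_identical(r$reasons, "washout")
  # exactly at the boundary: still inside the washout
  ph <- rbind(f$pharmacy, ph_fix(-183L))
  expect_false(check_eligibility(f$patient, ph, f$medical, f$enrollment,
                                 f$index)$eligible)
  # one day earlier: clean
  ph <- rbind(f$pharmacy, ph_fix(-184L))
  expect_true(check_eligibility(f$patient, ph, f$medical, f$enrollment,
                                f$index)$eligible)
  # psychotherapy procedure in the washout also fails
  md <- rbind(f$medical, med_fix(-50L, icd = "4659", proc = "90834"))
  expect_identical(check_eligibility(f$patient, f$pharmacy, md, f$enrollment,
                                     f$index)$reasons, "washout")
})

test_that("age, refill-gap and enrollment failures are reported with reasons", {
  f <- eligible_fixture()
  r <- check_eligibility(patient_fix(age = 17), f$pharmacy, f$medical,
                         f$enrollment, f$index)
  expect_identical(r$reasons, "age")
  expect_identical(check_eligibility(patient_fix(age = 64), f$pharmacy,
                                     f$medical, f$enrollment,
                                     f$index)$reasons, "age")
  # single fill: no qualifying refill
  r <- check_eligibility(f$patient, ph_fix(0L), f$medical, f$enrollment,
                         f$index)
  expect_identical(r$reasons, "refill_gap")
  # second fill 61 days after a 30-day supply: gap 31 > 30
  ph <- rbind(ph_fix(0L), ph_fix(61L))
  expect_identical(check_eligibility(f$patient, ph, f$medical, f$enrollment,
                                     f$index)$reasons, "refill_gap")
  # gap exactly 30 passes
  ph <- rbind(ph_fix(0L), ph_fix(60L))
  expect_true(check_eligibility(f$patient, ph, f$medical, f$enrollment,
                                f$index)$eligible)
  # enrollment stopping short of follow-up
  en <- enroll_fix(-400L, 500L)
  expect_identical(check_eligibility(f$patient, f$pharmacy, f$medical, en,
                                     f$index)$reasons, "enrollment")
  # ... but decedents only need coverage until death
  pat <- patient_fix(death_date = ORIGIN + 450L)
  expect_true(check_eligibility(pat, f$pharmacy, f$medical, en,
                                f$index)$eligible)
})

test_that("exclusion diagnoses apply at any time, drugs only in the washout", {
  f <- eligible_fixture()
  # bipolar code 10 months after index: excluded
  md <- rbind(f$medical, med_fix(300L, icd = "29640"))
  r <- apply_exclusions(f$patient, f$pharmacy, md, index_date = f$index)
  expect_true(r$excluded)
  expect_identical(r$reasons, "exclusion_diagnosis")
  # lithium 7 months before index: outside the washout, not excluded
  ph <- rbind(f$pharmacy, ph_fix(-213L, drug = "lithium", class = "lithium"))
  expect_false(apply_exclusions(f$patient, ph, f$medical,
                                index_date = f$index)$excluded)
  # lithium 100 days before index: excluded
  ph <- rbind(f$pharmacy, ph_fix(-100L, drug = "lithium", class = "lithium"))
  expect_true(apply_exclusions(f$patient, ph, f$medical,
                               index_date = f$index)$excluded)
  # ECT procedure in the washout: excluded
  md <- rbind(f$medical, med_fix(-20L, icd = "4659", proc = "ECT"))
  expect_identical(apply_exclusions(f$patient, f$pharmacy, md,
                                    index_date = f$index)$reasons,
                   "exclusion_procedure")
  # clean record: not excluded
  expect_false(apply_exclusions(f$patient, f$pharmacy, f$medical,
                                index_date = f$index)$excluded)
})

test_that("claims referencing unknown patients fail hard", {
  b <- generate_claims(simulation_config(5, seed = 1))
  b$pharmacy_claims$patient_id[1] <- "GHOST"
  expect_error(build_cohort(b), "unknown patient")
})

test_that("cohort records re-pass eligibility and the disposition conserves patients", {
  b <- generate_claims(simulation_config(120, death_fraction = 0.05,
                                         disenroll_fraction = 0.1, seed = 13))
  cb <- build_cohort(b)
  expect_identical(sum(cb$disposition), nrow(b$patients))
  sp_ph <- split(b$pharmacy_claims, b$pharmacy_claims$patient_id)
  sp_md <- split(b$medical_claims, b$medical_claims$patient_id)
  sp_en <- split(b$enrollment, b$enrollment$patient_id)
  for (i in seq_len(nrow(cb$cohort))) {
    pid <- cb$cohort$patient_id[i]
    pat <- b$patients[b$patients$patient_id == pid, ]
    el <- check_eligibility(pat, sp_ph[[pid]], sp_md[[pid]], sp_en[[pid]],
                            cb$cohort$index_date[i])
    ex <- apply_exclusions(pat, sp_ph[[pid]], sp_md[[pid]],
                           index_date = cb$cohort$index_date[i])
    expect_true(el$eligible)
    expect_false(ex$excluded)
  }
  # deliberately disenrolled stress patients are not eligible
  gt <- b$ground_truth
  dis <- gt$patient_id[gt$disenrolled & !gt$died]
  expect_false(any(dis %in% cb$cohort$patient_id))
})

test_that("covariate extraction bins age and windows the baseline flags", {
  f <- eligible_fixture()
  rec <- function(age) list(patient_id = "p1", index_date = f$index,
                            age_at_index = age, sex = "female")
  md <- rbind(f$medical, med_fix(-200L, icd = "30000"))
  cov <- extract_baseline_covariates(rec(24), md)
  expect_identical(as.character(cov$age_group), "18-24")
  expect_true(cov$anxiety)
  expect_false(cov$ptsd)
  expect_identical(cov$diagnosis_category, "300.X")
  expect_identical(as.character(extract_baseline_covariates(rec(25),
                                                            md)$age_group),
                   "25-34")
  # anxiety 13 months before index is outside the baseline window
  md2 <- rbind(f$medical, med_fix(-395L, icd = "30000"))
  expect_false(extract_baseline_covariates(rec(40), md2)$anxiety)
  expect_error(extract_baseline_covariates(rec(70), md), "18-63")
})

test_that("diagnosis category prefers the claim nearest the index, ties by code order", {
  f <- eligible_fixture()
  rec <- list(patient_id = "p1", index_date = f$index, age_at_index = 40,
              sex = "female")
  md <- rbind(med_fix(20L, icd = "311"), med_fix(5L, icd = "3090"))
  expect_identical(extract_baseline_covariates(rec, md)$diagnosis_category,
                   "309.X")
  # equidistant claims: 296.X outranks 311.X
  md <- rbind(med_fix(5L, icd = "311"), med_fix(-5L, icd = "29622"))
  expect_identical(extract_baseline_covariates(rec, md)$diagnosis_category,
                   "296.X")
})
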