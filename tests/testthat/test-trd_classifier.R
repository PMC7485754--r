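test_that("switch and augmentation transition boundaries are inclusive as published", {
  d0 <- ORIGIN
  cls <- function(gap, covered) classify_drug_transition(d0, covered, d0 + gap)
  # switch pathway: failure iff gap in [29, 180]
  expect_identical(cls(28L, FALSE), "no_failure")
  expect_identical(cls(29L, FALSE), "switch_failure")
  expect_identical(cls(180L, FALSE), "switch_failure")
  expect_identical(cls(181L, FALSE), "no_failure")
  # augmentation pathway: Day 1-14 joins the regimen, Day 15+ is a failure
  expect_identical(cls(0L, TRUE), "same_regimen")
  expect_identical(cls(13L, TRUE), "same_regimen")   # Day 14
  expect_identical(cls(14L, TRUE), "augmentation_failure")  # Day 15
  expect_error(classify_drug_transition(d0, FALSE, d0 - 1L), "precedes")
  # interval form of the coverage argument
  cov <- data.frame(start = d0, end = d0 + 29L)
  expect_identical(classify_drug_transition(d0, cov, d0 + 20L),
                   "augmentation_failure")
  # one day past the covered interval: switch pathway, qualifying gap
  expect_identical(classify_drug_transition(d0, cov, d0 + 30L),
                   "switch_failure")
})

test_that("treatment episodes end at a >180-day supply gap", {
  # contiguous monthly fills: one episode over the full covered span
  ph <- rbind(ph_fix(0L), ph_fix(30L), ph_fix(60L))
  ep <- build_treatment_episode(ph, ORIGIN)
  expect_identical(as.integer(ep$end - ep$start), 89L)
  expect_identical(length(ep$regimens), 1L)
  # a fill 219 uncovered days after supply ends is a new episode
  ph <- rbind(ph_fix(0L), ph_fix(249L))
  ep <- build_treatment_episode(ph, ORIGIN)
  expect_identical(as.integer(ep$end - ep$start), 29L)
  expect_identical(nrow(ep$claims), 1L)
  # a single fill
  ep <- build_treatment_episode(ph_fix(0L), ORIGIN)
  expect_identical(as.integer(ep$end - ep$start), 29L)
  expect_error(build_treatment_episode(ph_fix(10L), ORIGIN), "index")
})

test_that("dose adequacy uses the inclusive drug-specific minimum over the regimen", {
  reg <- list(line = 1L, start = ORIGIN, end = ORIGIN + 59L,
              drugs = "sertraline", roles = "core_antidepressant",
              failure_mode = "none")
  tbl <- default_dose_table()
  expect_true(assess_adequate_dose(reg, ph_fix(0L, dose = 50), tbl))
  expect_false(assess_adequate_dose(reg, ph_fix(0L, dose = 25), tbl))
  # titration crossing the minimum mid-regimen qualifies
  titr <- rbind(ph_fix(0L, dose = 25), ph_fix(30L, dose = 50))
  expect_true(assess_adequate_dose(reg, titr, tbl))
  reg$drugs <- "unobtainium"
  expect_error(assess_adequate_dose(reg, ph_fix(0L, drug = "unobtainium"),
                                    tbl), "unobtainium")
})

test_that("the resistance label composes the failure rules as published", {
  # A fails by switch at day 30, B fails by augmentation on Day 20: resistant
  ph <- rbind(ph_fix(0L, "sertraline", dose = 50),
              ph_fix(30L, "fluoxetine", dose = 20),
              ph_fix(60L, "fluoxetine", dose = 20),
              ph_fix(49L, "quetiapine", class = "antipsychotic", dose = NA))
  cls <- classify_trd(build_treatment_episode(ph, ORIGIN))
  expect_true(cls$trd)
  expect_identical(cls$n_regimens, 3L)
  expect_identical(cls$audit$failure_mode, c("switch", "augmentation", "none"))
  # first switch after only 20 days: drug A never an adequate-duration
  # failure, so the chain only reaches two lines
  ph <- rbind(ph_fix(0L, "sertraline", dose = 50, supply = 14L),
              ph_fix(20L, "fluoxetine", dose = 20, supply = 14L),
              ph_fix(60L, "citalopram", dose = 20))
  cls <- classify_trd(build_treatment_episode(ph, ORIGIN))
  expect_false(cls$trd)
  expect_identical(cls$n_regimens, 2L)
  # two regimens are never enough
  ph <- rbind(ph_fix(0L, "sertraline", dose = 50),
              ph_fix(40L, "fluoxetine", dose = 20))
  expect_false(classify_trd(build_treatment_episode(ph, ORIGIN))$trd)
  # an inadequate first-line dose blocks the label even with three lines
  ph <- rbind(ph_fix(0L, "sertraline", dose = 25),
              ph_fix(40L, "fluoxetine", dose = 20),
              ph_fix(70L, "fluoxetine", dose = 20),
              ph_fix(59L, "quetiapine", class = "antipsychotic", dose = NA))
  cls <- classify_trd(build_treatment_episode(ph, ORIGIN))
  expect_identical(cls$n_regimens, 3L)
  expect_false(cls$trd)
})

test_that("classification agrees with a brute-force rule evaluator on day grids", {
  run_both <- function(ph) {
    a <- classify_trd(build_treatment_episode(ph, ORIGIN))
    b <- brute_force_trd(ph, ORIGIN)
    expect_identical(a$n_regimens, b$n_lines,
                     info = paste(ph$dispense_date, collapse = ","))
    expect_identical(a$trd, b$trd,
                     info = paste(ph$dispense_date, collapse = ","))
  }
  # one transition event over the full day grid
  for (d1 in seq(1L, 400L, by = 3L)) {
    run_both(rbind(ph_fix(0L, "sertraline", dose = 50, supply = 28L),
                   ph_fix(d1, "fluoxetine", dose = 20, supply = 28L)))
  }
  # two antidepressant transitions on a coarser grid
  for (d1 in seq(5L, 220L, by = 17L)) {
    for (off in seq(7L, 210L, by = 23L)) {
      run_both(rbind(ph_fix(0L, "sertraline", dose = 50, supply = 28L),
                     ph_fix(d1, "fluoxetine", dose = 20, supply = 28L),
                     ph_fix(d1 + off, "citalopram", dose = 20, supply = 28L)))
    }
  }
  # augmentation event then an antidepressant
  for (d1 in seq(2L, 80L, by = 7L)) {
    for (off in seq(10L, 200L, by = 31L)) {
      run_both(rbind(ph_fix(0L, "sertraline", dose = 50, supply = 90L),
                     ph_fix(d1, "lithium", class = "lithium", dose = NA,
                            supply = 28L),
                     ph_fix(d1 + off, "fluoxetine", dose = 20, supply = 28L)))
    }
  }
})

test_that("a qualifying switch gap anywhere in 29-180 preserves the label", {
  make <- function(g) {
    rbind(ph_fix(0L, "sertraline", dose = 50, supply = 28L),
          ph_fix(g, "fluoxetine", dose = 20, supply = 28L),
          ph_fix(g + 28L, "fluoxetine", dose = 20, supply = 28L),
          ph_fix(g + 40L, "quetiapine", class = "antipsychotic", dose = NA))
  }
  for (g in c(29L, 45L, 90L, 133L, 180L)) {
    cls <- classify_trd(build_treatment_episode(make(g), ORIGIN))
    expect_true(cls$trd, info = paste("gap", g))
  }
})

test_that("the classifier recovers every scripted ground-truth label", {
  b <- generate_claims(simulation_config(400, seed = 21))
  cb <- build_cohort(b)
  co <- classify_cohort(cb$cohort, b$pharmacy_claims)
  gt <- b$ground_truth
  expect_identical(co$trd, gt$trd_true[match(co$patient_id, gt$patient_id)])
})
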