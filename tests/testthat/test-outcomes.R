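idx_one <- function(id = "p1") data.frame(patient_id = id, index_date = ORIGIN)

test_that("patients without claims get all-zero annual rows", {
  ann <- annualize_outcomes(med_fix(0L)[0, ], ph_fix(0L)[0, ], idx_one())
  expect_identical(nrow(ann), 2L)
  num <- vapply(ann[, -(1:2)], is.numeric, logical(1)) |
    vapply(ann[, -(1:2)], is.logical, logical(1))
  expect_true(all(unlist(ann[, -(1:2)]) == 0))
})

test_that("inpatient stays are assigned to years by service start", {
  md <- med_fix(99L, setting = "inpatient", los = 5L)  # starts day 100
  ann <- annualize_outcomes(md, ph_fix(0L)[0, ], idx_one())
  y1 <- ann[ann$follow_year == 1, ]; y2 <- ann[ann$follow_year == 2, ]
  expect_identical(y1$hospital_los, 5)
  expect_true(y1$any_hospitalization)
  expect_identical(y2$hospital_los, 0)
  expect_false(y2$any_hospitalization)
  expect_identical(y1$outpatient_visits, 0)
})

test_that("identity inflation reproduces raw claim sums and identities hold", {
  md <- rbind(med_fix(10L, payer = 100, patient = 20),
              med_fix(400L, payer = 50, patient = 5),
              med_fix(-100L, payer = 30, patient = 3))
  ph <- rbind(ph_fix(5L), ph_fix(370L))   # payer 10, patient 2 each
  ann <- annualize_outcomes(md, ph, idx_one(), years = 0:2)
  y0 <- ann[ann$follow_year == 0, ]; y1 <- ann[ann$follow_year == 1, ]
  y2 <- ann[ann$follow_year == 2, ]
  expect_equal(y1$payer_medical, 100); expect_equal(y1$payer_pharmacy, 10)
  expect_equal(y1$total_healthcare, 100 + 20 + 10 + 2)
  expect_equal(y2$total_healthcare, 50 + 5 + 10 + 2)
  expect_equal(y0$payer_medical, 30)
  # an explicit multiplier scales only matching calendar years
  infl <- c("2013" = 2)
  ann2 <- annualize_outcomes(md, ph, idx_one(), years = 1L,
                             inflation_table = infl)
  expect_equal(ann2$payer_medical, 200)
})

test_that("accounting identities hold on every generated patient-year", {
  b <- generate_claims(simulation_config(80, seed = 17))
  gt <- b$ground_truth
  ann <- annualize_outcomes(b$medical_claims, b$pharmacy_claims,
                            data.frame(patient_id = gt$patient_id,
                                       index_date = gt$index_date),
                            years = 0:2)
  expect_equal(ann$payer_total, ann$payer_medical + ann$payer_pharmacy)
  expect_equal(ann$patient_total, ann$patient_medical + ann$patient_rx)
  expect_equal(ann$total_healthcare, ann$payer_total + ann$patient_total)
  expect_true(all(ann$hospital_los >= 0))
  expect_true(all(ann$outpatient_visits >= 0))
})

test_that("the count model agrees with a Poisson fit in the no-dispersion limit", {
  set.seed(5)
  n <- 600
  trd <- rep(c(TRUE, FALSE), each = n / 2)
  base <- rpois(n, 4)
  y <- rpois(n, exp(log(5) + 0.05 * base))
  r <- fit_count_model(y, trd, base)
  pfit <- glm(y ~ trd + base, family = poisson(),
              data = data.frame(y = y, trd = as.integer(trd), base = base))
  d1 <- data.frame(trd = 1L, base = base); d0 <- data.frame(trd = 0L, base = base)
  mu1 <- mean(predict(pfit, newdata = transform(d1, y = 0), type = "response"))
  mu0 <- mean(predict(pfit, newdata = transform(d0, y = 0), type = "response"))
  expect_equal(r$mean_trd, mu1, tolerance = 0.01)
  expect_equal(r$mean_control, mu0, tolerance = 0.01)
  expect_error(fit_count_model(rep(0, 10), rep(c(TRUE, FALSE), 5), rep(0, 10)),
               "all-zero")
})

test_that("the linear cost model matches a hand-solved least-squares oracle", {
  # 6-row fixture; normal equations solved directly, independent of lm
  d <- data.frame(y = c(100, 140, 90, 210, 260, 240),
                  trd = c(0, 0, 0, 1, 1, 1),
                  base = c(80, 120, 70, 90, 150, 130))
  X <- cbind(1, d$trd, d$base)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  mu1 <- mean(cbind(1, 1, d$base) %*% beta)
  mu0 <- mean(cbind(1, 0, d$base) %*% beta)
  r <- fit_cost_model(d$y, d$trd, d$base, family = "linear_normal")
  expect_equal(r$difference, mu1 - mu0, tolerance = 1e-10)
  expect_equal(r$mean_trd, mu1, tolerance = 1e-10)
  expect_equal(r$mean_control, mu0, tolerance = 1e-10)
})

test_that("gamma cost model shifts exact zeros and rejects negatives", {
  set.seed(8)
  y <- c(rgamma(50, 2, 0.001), 0, 0)
  trd <- rep(c(TRUE, FALSE), 26)
  base <- rgamma(52, 2, 0.001)
  r <- fit_cost_model(y, trd, base)
  expect_identical(r$zero_adjusted, 2L)
  expect_gt(r$mean_trd, 0)
  expect_error(fit_cost_model(c(-1, y[-1]), trd, base), "negative")
  expect_error(fit_cost_model(rep(0, 10), rep(c(TRUE, FALSE), 5), rep(1, 10)),
               "positive support")
})

test_that("the bootstrap is deterministic, degenerate-safe and near the t-interval", {
  d <- data.frame(y = rnorm(50), trd = rep(c(TRUE, FALSE), 25))
  # constant estimator: zero-width interval at the constant
  r <- bootstrap_difference(function(dd) 3.5, d, iterations = 50, seed = 1)
  expect_equal(r$ci, c(3.5, 3.5))
  # same seed, same bounds; different seed differs
  est <- function(dd) mean(dd$y[dd$trd]) - mean(dd$y[!dd$trd])
  r1 <- bootstrap_difference(est, d, 200, seed = 10)
  r2 <- bootstrap_difference(est, d, 200, seed = 10)
  r3 <- bootstrap_difference(est, d, 200, seed = 11)
  expect_identical(r1$ci, r2$ci)
  expect_false(identical(r1$ci, r3$ci))
  # percentile CI close to the t-interval for a normal mean
  set.seed(99)
  x <- data.frame(y = rnorm(200, mean = 5, sd = 1))
  rb <- bootstrap_difference(function(dd) mean(dd$y), x, 1000, seed = 3,
                             strata = rep(1, 200))
  tt <- t.test(x$y)$conf.int
  expect_lt(max(abs(rb$ci - tt) / abs(tt)), 0.10)
  expect_lt(abs(diff(rb$ci) - diff(tt)) / diff(tt), 0.15)
  # estimators that keep failing abort with a clear message
  expect_error(bootstrap_difference(function(dd) stop("boom"), d, 20, seed = 1),
               "10%")
})

test_that("independence GEE reproduces the ordinary logistic fit", {
  set.seed(12)
  n <- 500
  d <- data.frame(x = rnorm(n), z = rbinom(n, 1, 0.4))
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x + 0.4 * d$z))
  g <- gee_logit(y ~ x + z, d, id = seq_len(n), corstr = "independence")
  f <- glm(y ~ x + z, data = d, family = binomial())
  expect_equal(unname(g$coefficients), unname(coef(f)), tolerance = 1e-5)
  expect_identical(g$alpha, 0)
})

test_that("the repeated-measures model recovers year-specific odds ratios", {
  set.seed(33)
  n <- 4000
  trd <- rep(rep(c(1, 0), each = n / 2), times = 2)
  year <- rep(c(1, 2), each = n)
  id <- rep(sprintf("p%04d", 1:n), times = 2)
  u <- rep(rnorm(n, sd = 0.6), times = 2)        # shared frailty
  eta <- qlogis(0.2) + log(1.7) * trd * (year == 1) +
    log(1.4) * trd * (year == 2) + u
  y <- rbinom(2 * n, 1, plogis(eta))
  base <- rep(rbinom(n, 1, 0.2), times = 2)
  elix <- rep(rpois(n, 1.5), times = 2)
  r <- fit_repeated_logistic(y, trd, year, base, elix, id)
  expect_gt(r$fit$alpha, 0.02)   # the shared frailty induces correlation
  expect_lt(abs(r$or_table$or[1] - 1.7) / 1.7, 0.15)
  expect_lt(abs(r$or_table$or[2] - 1.4) / 1.4, 0.15)
  expect_true(all(r$or_table$lower <= r$or_table$or &
                    r$or_table$or <= r$or_table$upper))
  expect_error(fit_repeated_logistic(rep(0, 8), rep(c(1, 0), 4),
                                     rep(1:2, each = 4), rep(0, 8),
                                     rep(1, 8), rep(1:4, 2)), "constant")
})

test_that("diagnosis subgroups are fitted or skipped with reasons", {
  set.seed(3)
  n <- 120
  trd <- rep(c(TRUE, FALSE), n / 2)
  y <- rgamma(n, 2, 0.001); base <- rgamma(n, 2, 0.001)
  # everyone in one category: one result, three skip records
  r <- subgroup_costs_by_diagnosis(y, trd, base, rep("296.X", n))
  expect_identical(names(r$results), "296.X")
  expect_identical(nrow(r$skipped), 3L)
  # a subgroup with one resistant patient is skipped with a reason
  cat2 <- rep("296.X", n); cat2[trd][-1] <- "311.X"
  cat2[trd][1] <- "300.X"
  r2 <- subgroup_costs_by_diagnosis(y, trd, base, cat2)
  expect_true("300.X" %in% r2$skipped$category)
  expect_match(r2$skipped$reason[r2$skipped$category == "300.X"],
               "fewer than 2")
})

test_that("reports render with headers when empty and rows when populated", {
  d <- withr::local_tempdir()
  paths <- render_reports(d)
  expect_true(all(file.exists(paths)))
  expect_identical(nrow(read.csv(file.path(d, "utilization.csv"))), 0L)
  one <- data.frame(outcome = "outpatient_visits", year = 1:2,
                    family = "negative_binomial", n_trd = 10, n_control = 40,
                    mean_trd = 11, mean_control = 8.5, estimate = 2.5,
                    ratio = 1.3, ci_lower = 1.8, ci_upper = 3.1)
  render_reports(d, utilization = one)
  expect_identical(nrow(read.csv(file.path(d, "utilization.csv"))), 2L)
  txt <- readLines(file.path(d, "summary.txt"))
  expect_true(any(grepl("outpatient_visits", txt)))
})
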