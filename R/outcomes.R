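#' Aggregate utilization and costs per patient-year
#'
#' Follow-up year 1 covers post-index days 1-365 (the index date is day 1),
#' year 2 days 366-730; passing `years = 0` aggregates the 12-month
#' pre-index baseline instead. Visits and stays are assigned to years by
#' service start date, inpatient length of stay is summed over stays
#' starting in the year, and every cost is multiplied by the inflation
#' factor of the claim's calendar year (identity by default). Patients with
#' no claims in a year receive all-zero rows. Cost accounting identities
#' hold on every row: payer total = payer medical + payer pharmacy, patient
#' total = patient medical + patient rx, total healthcare = payer + patient.
#'
#' @param medical_claims,pharmacy_claims claims tables.
#' @param index_dates data.frame with `patient_id` and `index_date` (the
#'   patient universe: one output row per patient and year).
#' @param years integer subset of `c(0, 1, 2)`.
#' @param inflation_table optional named numeric vector of multipliers by
#'   calendar year (e.g. `c("2013" = 1.06)`); missing years default to 1.
#' @param enrollment optional; when supplied with `patients`, claims outside
#'   any enrollment spell of a non-decedent are flagged in an `audit`
#'   attribute (and still counted: claims data are authoritative).
#' @param patients optional patients table (for death dates).
#' @return data.frame with one row per patient-year.
#' @export
annualize_outcomes <- function(medical_claims, pharmacy_claims, index_dates,
                               years = c(1L, 2L), inflation_table = NULL,
                               enrollment = NULL, patients = NULL) {
  stopifnot(all(years %in% 0:2))
  ids <- index_dates$patient_id
  idx <- as.Date(index_dates$index_date)
  names(idx) <- ids

  year_of <- function(off) {
    ifelse(off >= -365L & off <= -1L, 0L,
           ifelse(off >= 0L & off <= 364L, 1L,
                  ifelse(off >= 365L & off <= 729L, 2L, NA_integer_)))
  }
  infl <- function(dates) {
    if (is.null(inflation_table)) return(rep(1, length(dates)))
    f <- inflation_table[format(as.Date(dates), "%Y")]
    f[is.na(f)] <- 1
    unname(f)
  }

  md <- medical_claims[medical_claims$patient_id %in% ids, , drop = FALSE]
  ph <- pharmacy_claims[pharmacy_claims$patient_id %in% ids, , drop = FALSE]
  md_off <- as.integer(as.Date(md$service_start) - idx[md$patient_id])
  ph_off <- as.integer(as.Date(ph$dispense_date) - idx[ph$patient_id])
  md$year <- year_of(md_off)
  ph$year <- year_of(ph_off)
  md <- md[!is.na(md$year) & md$year %in% years, , drop = FALSE]
  ph <- ph[!is.na(ph$year) & ph$year %in% years, , drop = FALSE]

  if (!is.null(enrollment) && !is.null(patients)) {
    dd <- as.Date(patients$death_date)
    names(dd) <- patients$patient_id
    in_spell <- function(pid, d) {
      sp <- enrollment[enrollment$patient_id == pid, , drop = FALSE]
      any(as.Date(sp$start) <= d & as.Date(sp$end) >= d)
    }
    audit <- list()
    for (i in seq_len(nrow(md))) {
      pid <- md$patient_id[i]; d <- as.Date(md$service_start[i])
      if (!is.na(dd[pid])) next
      if (!in_spell(pid, d))
        audit[[length(audit) + 1L]] <- data.frame(
          patient_id = pid, date = d, table = "medical_claims",
          stringsAsFactors = FALSE)
    }
    if (length(audit))
      warning(sprintf("%d claim(s) outside enrollment for non-decedents; counted anyway",
                      length(audit)), call. = FALSE)
  }

  key_md <- paste(md$patient_id, md$year, sep = "\r")
  key_ph <- paste(ph$patient_id, ph$year, sep = "\r")
  grid <- expand.grid(patient_id = ids, follow_year = sort(unique(years)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key_g <- paste(grid$patient_id, grid$follow_year, sep = "\r")

  acc <- function(x, key) {
    if (!length(x)) return(numeric(length(key_g)))
    s <- rowsum(x, key)
    out <- s[match(key_g, rownames(s)), 1]
    out[is.na(out)] <- 0
    unname(out)
  }
  f_md <- infl(md$service_start)
  f_ph <- infl(ph$dispense_date)
  is_out <- md$setting == "outpatient"
  is_ed <- md$setting == "ed"
  is_in <- md$setting == "inpatient"
  los <- as.integer(as.Date(md$service_end) - as.Date(md$service_start)) + 1L

  res <- grid
  res$outpatient_visits <- acc(as.numeric(is_out), key_md)
  res$any_ed <- acc(as.numeric(is_ed), key_md) > 0
  res$any_hospitalization <- acc(as.numeric(is_in), key_md) > 0
  res$hospital_los <- acc(ifelse(is_in, los, 0L), key_md)
  res$payer_medical <- acc(md$payer_cost * f_md, key_md)
  res$payer_pharmacy <- acc(ph$payer_cost * f_ph, key_ph)
  res$patient_medical <- acc(md$patient_cost * f_md, key_md)
  res$patient_rx <- acc(ph$patient_cost * f_ph, key_ph)
  res$payer_total <- res$payer_medical + res$payer_pharmacy
  res$patient_total <- res$patient_medical + res$patient_rx
  res$total_healthcare <- res$payer_total + res$patient_total
  res
}

#' Baseline-period outcomes
#'
#' Convenience wrapper: [annualize_outcomes()] over the 12-month pre-index
#' baseline (`years = 0`).
#'
#' @inheritParams annualize_outcomes
#' @return data.frame, one row per patient.
#' @export
baseline_outcomes <- function(medical_claims, pharmacy_claims, index_dates,
                              inflation_table = NULL) {
  annualize_outcomes(medical_claims, pharmacy_claims, index_dates,
                     years = 0L, inflation_table = inflation_table)
}

new_model_result <- function(outcome, family, n1, n0, mean_trd, mean_control,
                             difference, ratio = NA_real_,
                             ci = c(NA_real_, NA_real_), iterations = 0L,
                             seed = NULL, extra = list()) {
  if (all(is.finite(ci)) && ci[1] > ci[2]) stopf("CI lower bound exceeds upper")
  out <- c(list(outcome = outcome, family = family,
                n = c(trd = n1, control = n0),
                mean_trd = mean_trd, mean_control = mean_control,
                difference = difference, ratio = ratio,
                ci_lower = ci[1], ci_upper = ci[2],
                iterations = iterations, seed = seed), extra)
  class(out) <- "trd_model_result"
  out
}

#' @export
print.trd_model_result <- function(x, ...) {
  cat(sprintf("%s (%s): adjusted means %.3f vs %.3f, difference %.3f",
              x$outcome, x$family, x$mean_trd, x$mean_control, x$difference))
  if (is.finite(x$ci_lower))
    cat(sprintf(" (95%% CI %.3f to %.3f, %d bootstrap iterations)",
                x$ci_lower, x$ci_upper, x$iterations))
  cat("\n")
  invisible(x)
}

# Adjusted group means by recycled predictions: predict for the full sample
# with the exposure toggled, average on the response scale.
recycled_means <- function(fit, data) {
  d1 <- data; d1$trd <- 1L
  d0 <- data; d0$trd <- 0L
  c(mu1 = mean(stats::predict(fit, newdata = d1, type = "response")),
    mu0 = mean(stats::predict(fit, newdata = d0, type = "response")))
}

#' Adjusted utilization model (negative binomial)
#'
#' Log-link negative-binomial GLM of a follow-up count on
#' treatment-resistance status adjusted for the baseline value of the same
#' variable. Adjusted group means come from recycled predictions; the
#' difference CI from a stratified patient-level percentile bootstrap. If
#' the negative-binomial fit fails to converge (e.g. data with no
#' overdispersion), a Poisson GLM is used and reported as such.
#'
#' @param counts non-negative follow-up counts, one per patient.
#' @param trd logical/0-1 exposure.
#' @param baseline baseline counts.
#' @param iterations bootstrap iterations (0 = no CI).
#' @param seed bootstrap seed.
#' @return a `trd_model_result` with adjusted means, difference and ratio.
#' @export
fit_count_model <- function(counts, trd, baseline, iterations = 0L,
                            seed = NULL) {
  trd <- as.integer(as.logical(trd))
  if (min(table(trd)) < 2L) stopf("need at least 2 patients per group")
  if (all(counts == 0)) stopf("outcome is all-zero in both arms")
  d <- data.frame(y = counts, trd = trd, baseline = baseline)
  fit_one <- function(dd) {
    fam <- "negative_binomial"
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ trd + baseline, data = dd)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fam <- "poisson"
      fit <- stats::glm(y ~ trd + baseline, data = dd, family = stats::poisson())
    }
    mu <- recycled_means(fit, dd)
    list(mu = mu, family = fam)
  }
  est <- fit_one(d)
  ci <- c(NA_real_, NA_real_)
  if (iterations > 0) {
    ci <- bootstrap_difference(function(dd) {
      mu <- fit_one(dd)$mu
      mu["mu1"] - mu["mu0"]
    }, d, iterations = iterations, seed = seed, strata = d$trd)$ci
  }
  new_model_result("count", est$family, sum(trd == 1), sum(trd == 0),
                   est$mu[["mu1"]], est$mu[["mu0"]],
                   est$mu[["mu1"]] - est$mu[["mu0"]],
                   ratio = est$mu[["mu1"]] / est$mu[["mu0"]],
                   ci = ci, iterations = iterations, seed = seed)
}

#' Adjusted cost model (gamma or linear)
#'
#' Log-link gamma GLM (or, as a sensitivity family, an ordinary linear
#' model) of annual cost on treatment-resistance status adjusted for the
#' baseline cost. The gamma family requires positive outcomes: exact zeros
#' are shifted by half the smallest positive cost, and the number of
#' adjusted observations is reported. Adjusted means by recycled
#' predictions; CI by stratified patient-level percentile bootstrap.
#'
#' @param costs non-negative annual costs.
#' @param trd logical/0-1 exposure.
#' @param baseline baseline costs.
#' @param family `"gamma_log"` or `"linear_normal"`.
#' @param iterations,seed bootstrap controls.
#' @return a `trd_model_result`.
#' @export
fit_cost_model <- function(costs, trd, baseline,
                           family = c("gamma_log", "linear_normal"),
                           iterations = 0L, seed = NULL) {
  family <- match.arg(family)
  if (any(costs < 0)) stopf("negative costs are not allowed")
  trd <- as.integer(as.logical(trd))
  if (min(table(trd)) < 2L) stopf("need at least 2 patients per group")
  zero_adjusted <- 0L
  y <- costs
  if (family == "gamma_log") {
    if (all(y == 0)) stopf("all costs are zero; gamma family needs positive support")
    zero_adjusted <- sum(y == 0)
    if (zero_adjusted > 0) y[y == 0] <- min(y[y > 0]) / 2
  }
  d <- data.frame(y = y, trd = trd, baseline = baseline)
  fit_one <- function(dd) {
    fit <- if (family == "gamma_log") {
      stats::glm(y ~ trd + baseline, data = dd,
                 family = stats::Gamma(link = "log"))
    } else {
      stats::lm(y ~ trd + baseline, data = dd)
    }
    recycled_means(fit, dd)
  }
  mu <- fit_one(d)
  ci <- c(NA_real_, NA_real_)
  if (iterations > 0) {
    ci <- bootstrap_difference(function(dd) {
      m <- fit_one(dd); m[["mu1"]] - m[["mu0"]]
    }, d, iterations = iterations, seed = seed, strata = d$trd)$ci
  }
  new_model_result("cost", family, sum(trd == 1), sum(trd == 0),
                   mu[["mu1"]], mu[["mu0"]], mu[["mu1"]] - mu[["mu0"]],
                   ratio = mu[["mu1"]] / mu[["mu0"]], ci = ci,
                   iterations = iterations, seed = seed,
                   extra = list(zero_adjusted = zero_adjusted))
}

#' Percentile bootstrap for an estimator
#'
#' Patient-level resampling stratified by arm (each stratum resampled with
#' replacement within itself), percentile 2.5/97.5 bounds. A resample on
#' which the estimator fails is redrawn and the failure counted; more than
#' 10% failures aborts.
#'
#' @param estimator function taking a resampled data.frame, returning a
#'   scalar.
#' @param data data.frame of patient-level rows.
#' @param iterations number of bootstrap resamples (>= 1).
#' @param seed RNG seed; the same seed yields identical bounds.
#' @param strata stratification vector (defaults to `data$trd` when present,
#'   else a single stratum).
#' @return list with `ci` (length-2 numeric), `estimates`, `failures`.
#' @export
bootstrap_difference <- function(estimator, data, iterations, seed = NULL,
                                 strata = NULL) {
  stopifnot(iterations >= 1)
  if (is.null(strata)) strata <- data$trd %||% rep(1L, nrow(data))
  groups <- split(seq_len(nrow(data)), strata)
  run <- function() {
    est <- numeric(iterations)
    failures <- 0L
    max_fail <- ceiling(0.1 * iterations)
    b <- 1L
    while (b <= iterations) {
      idx <- unlist(lapply(groups, function(g) g[sample.int(length(g),
                                                            replace = TRUE)]),
                    use.names = FALSE)
      v <- tryCatch(estimator(data[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
      if (is.na(v)) {
        failures <- failures + 1L
        if (failures > max_fail)
          stopf("bootstrap aborted: estimator failed on more than 10%% of resamples")
        next
      }
      est[b] <- v
      b <- b + 1L
    }
    list(est = est, failures = failures)
  }
  r <- if (is.null(seed)) run() else with_seed(seed, run())
  ci <- unname(stats::quantile(r$est, c(0.025, 0.975)))
  list(ci = ci, estimates = r$est, failures = r$failures)
}

#' Repeated-measures logistic model for binary utilization
#'
#' Marginal logistic model of an annual binary outcome (any ED visit, any
#' hospitalization) over both follow-up years: outcome on
#' treatment-resistance status, follow-up year, their interaction, the
#' baseline value of the outcome, and the baseline Elixhauser score, with
#' within-patient correlation handled by [gee_logit()] (exchangeable working
#' correlation by default) and robust variance. Year-specific odds ratios
#' are derived from the exposure and interaction terms with delta-method
#' CIs on the log scale.
#'
#' @param outcome 0/1 outcome, one row per patient-year.
#' @param trd,year,baseline,elixhauser covariates per row (`year` in
#'   `c(1, 2)`; `baseline` is the patient's baseline value of the outcome).
#' @param id patient identifier per row.
#' @param corstr working correlation.
#' @return object of class `trd_or_result`: list with `or_table`
#'   (year, or, lower, upper), `fit`, `n`.
#' @export
fit_repeated_logistic <- function(outcome, trd, year, baseline, elixhauser,
                                  id, corstr = c("exchangeable",
                                                 "independence")) {
  corstr <- match.arg(corstr)
  outcome <- as.integer(outcome)
  for (y in unique(year)) {
    if (length(unique(outcome[year == y])) < 2L)
      stopf("outcome is constant in year %s; odds ratios are undefined", y)
  }
  d <- data.frame(y = outcome, trd = as.integer(as.logical(trd)),
                  year2 = as.integer(year == 2),
                  baseline = as.numeric(baseline),
                  elixhauser = as.numeric(elixhauser))
  fit <- gee_logit(y ~ trd + year2 + trd:year2 + baseline + elixhauser,
                   d, id = id, corstr = corstr)
  b <- fit$coefficients; V <- fit$vcov
  l1 <- b["trd"]; v1 <- V["trd", "trd"]
  l2 <- b["trd"] + b["trd:year2"]
  v2 <- V["trd", "trd"] + V["trd:year2", "trd:year2"] +
    2 * V["trd", "trd:year2"]
  z <- stats::qnorm(0.975)
  or_table <- data.frame(
    year = c(1L, 2L),
    or = exp(c(l1, l2)),
    lower = exp(c(l1 - z * sqrt(v1), l2 - z * sqrt(v2))),
    upper = exp(c(l1 + z * sqrt(v1), l2 + z * sqrt(v2))))
  out <- list(or_table = or_table, fit = fit,
              n = length(unique(id)), corstr = corstr)
  class(out) <- "trd_or_result"
  out
}

#' @export
print.trd_or_result <- function(x, ...) {
  cat(sprintf("Repeated-measures logistic model (%s), %d patients\n",
              x$corstr, x$n))
  print(x$or_table, row.names = FALSE)
  invisible(x)
}

#' Cost differences by depression diagnosis category
#'
#' Fits the linear-family cost model within each diagnosis category (296.X,
#' 300.X, 309.X, 311.X). Categories with fewer than 2 patients in either arm
#' are skipped with a recorded reason.
#'
#' @param costs,trd,baseline per-patient vectors.
#' @param diagnosis_category category labels per patient.
#' @param iterations,seed bootstrap controls.
#' @return list with `results` (one `trd_model_result` per fitted category)
#'   and `skipped` (data.frame of category, reason).
#' @export
subgroup_costs_by_diagnosis <- function(costs, trd, baseline,
                                        diagnosis_category,
                                        iterations = 0L, seed = NULL) {
  cats <- c("296.X", "300.X", "309.X", "311.X")
  results <- list()
  skipped <- data.frame(category = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  trd <- as.logical(trd)
  for (cc in cats) {
    sel <- which(diagnosis_category == cc)
    n1 <- sum(trd[sel]); n0 <- sum(!trd[sel])
    if (n1 < 2L || n0 < 2L) {
      skipped <- rbind(skipped, data.frame(
        category = cc,
        reason = sprintf("fewer than 2 patients per arm (%d resistant, %d comparison)",
                         n1, n0),
        stringsAsFactors = FALSE))
      next
    }
    results[[cc]] <- fit_cost_model(costs[sel], trd[sel], baseline[sel],
                                    family = "linear_normal",
                                    iterations = iterations, seed = seed)
  }
  list(results = results, skipped = skipped)
}
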