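#' Configuration for the synthetic claims generator
#'
#' Defines the study conditions the generator emulates: cohort size, the
#' fraction of patients scripted onto a treatment-resistant trajectory, and
#' the multiplicative effects of treatment resistance on annual costs and
#' utilization. Defaults mirror the observed structure of a commercially
#' insured depression cohort: 13% treatment-resistant prevalence, mean annual
#' total healthcare cost near $8,800 in the comparison arm, about 8.5
#' outpatient visits in follow-up year 1 with a decay to two thirds of that
#' in year 2, 19% with an ED visit and 5% hospitalized per year, and
#' year-specific odds-ratio effects (ED 1.39/1.27, hospitalization
#' 1.73/1.43).
#'
#' @param n_patients number of patients to generate.
#' @param trd_trajectory_fraction target fraction scripted to satisfy the
#'   treatment-resistance definition (marginal; assignment is mildly
#'   covariate-dependent so that propensity matching has signal).
#' @param cost_effect_ratio multiplicative effect of the resistant trajectory
#'   on mean annual total cost.
#' @param utilization_effect_ratio multiplicative effect on mean annual
#'   outpatient-visit count.
#' @param baseline_cost_mean mean annual total cost (US$) in the comparison
#'   arm (and in the pre-index baseline year for everyone).
#' @param cost_shape gamma shape parameter for annual costs.
#' @param visit_mean mean outpatient visits per year in the comparison arm.
#' @param visit_dispersion negative-binomial dispersion (1/size) for visit
#'   counts.
#' @param year2_visit_decay multiplier on the visit mean in follow-up year 2.
#' @param ed_base_prob,hosp_base_prob annual probability of any ED visit /
#'   hospitalization in the comparison arm.
#' @param ed_effect_or,hosp_effect_or length-2 odds ratios (years 1 and 2)
#'   applied to the resistant arm.
#' @param death_fraction fraction of patients who die during follow-up.
#' @param disenroll_fraction fraction given a deliberately truncated
#'   enrollment spell (stress cases, flagged in ground truth).
#' @param patient_cost_share fraction of each claim's cost borne by the
#'   patient (deductible + copay + coinsurance).
#' @param seed integer RNG seed; identical config and seed give identical
#'   bundles.
#' @param study_window two dates bounding index dispensings.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients,
                              trd_trajectory_fraction = 0.13,
                              cost_effect_ratio = 1.40,
                              utilization_effect_ratio = 1.35,
                              baseline_cost_mean = 8800,
                              cost_shape = 1.5,
                              visit_mean = 8.5,
                              visit_dispersion = 0.30,
                              year2_visit_decay = 0.66,
                              ed_base_prob = 0.19,
                              hosp_base_prob = 0.05,
                              ed_effect_or = c(1.39, 1.27),
                              hosp_effect_or = c(1.73, 1.43),
                              death_fraction = 0.01,
                              disenroll_fraction = 0,
                              patient_cost_share = 0.15,
                              seed = 1L,
                              study_window = as.Date(c("2013-01-01",
                                                       "2014-09-30"))) {
  chk_prob <- function(x, nm, len = 1L) {
    if (length(x) != len || any(is.na(x)) || any(x < 0) || any(x > 1))
      stopf("invalid simulation_config: '%s' must be in [0, 1]", nm)
  }
  chk_pos <- function(x, nm, len = 1L) {
    if (length(x) != len || any(is.na(x)) || any(x <= 0))
      stopf("invalid simulation_config: '%s' must be strictly positive", nm)
  }
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0 ||
      n_patients != floor(n_patients))
    stopf("invalid simulation_config: 'n_patients' must be a non-negative integer")
  chk_prob(trd_trajectory_fraction, "trd_trajectory_fraction")
  chk_pos(cost_effect_ratio, "cost_effect_ratio")
  chk_pos(utilization_effect_ratio, "utilization_effect_ratio")
  chk_pos(baseline_cost_mean, "baseline_cost_mean")
  chk_pos(cost_shape, "cost_shape")
  chk_pos(visit_mean, "visit_mean")
  chk_pos(visit_dispersion, "visit_dispersion")
  chk_pos(year2_visit_decay, "year2_visit_decay")
  chk_prob(ed_base_prob, "ed_base_prob")
  chk_prob(hosp_base_prob, "hosp_base_prob")
  chk_pos(ed_effect_or, "ed_effect_or", 2L)
  chk_pos(hosp_effect_or, "hosp_effect_or", 2L)
  chk_prob(death_fraction, "death_fraction")
  chk_prob(disenroll_fraction, "disenroll_fraction")
  chk_prob(patient_cost_share, "patient_cost_share")
  if (length(seed) != 1L || is.na(seed))
    stopf("invalid simulation_config: 'seed' must be a single integer")
  study_window <- as.Date(study_window)
  if (length(study_window) != 2L || any(is.na(study_window)) ||
      study_window[1] > study_window[2])
    stopf("invalid simulation_config: 'study_window' must be two ordered dates")
  cfg <- list(n_patients = as.integer(n_patients),
              trd_trajectory_fraction = trd_trajectory_fraction,
              cost_effect_ratio = cost_effect_ratio,
              utilization_effect_ratio = utilization_effect_ratio,
              baseline_cost_mean = baseline_cost_mean,
              cost_shape = cost_shape,
              visit_mean = visit_mean,
              visit_dispersion = visit_dispersion,
              year2_visit_decay = year2_visit_decay,
              ed_base_prob = ed_base_prob,
              hosp_base_prob = hosp_base_prob,
              ed_effect_or = ed_effect_or,
              hosp_effect_or = hosp_effect_or,
              death_fraction = death_fraction,
              disenroll_fraction = disenroll_fraction,
              patient_cost_share = patient_cost_share,
              seed = as.integer(seed),
              study_window = study_window)
  class(cfg) <- "simulation_config"
  cfg
}

# Augmentation agents available to the generator, by class.
generator_augmentation_drugs <- function() {
  data.frame(drug_name = c("aripiprazole", "quetiapine", "lithium",
                           "liothyronine", "lamotrigine", "methylphenidate"),
             drug_class = c("antipsychotic", "antipsychotic", "lithium",
                            "thyroid_hormone", "anticonvulsant",
                            "psychostimulant"),
             stringsAsFactors = FALSE)
}

# --- scripted pharmacy templates ------------------------------------------
# Each template returns a data.frame(day, drug, class, dose, supply) of
# dispensings relative to the index date (day 0 = index dispensing), built so
# that the treatment-episode classifier reaches the intended label by
# construction. `ads` is a vector of >= 3 distinct antidepressant names,
# `dose_tbl` the minimum-dose table.

template_pharmacy <- function(template, ads, aug, dose_tbl) {
  amin <- function(d) unname(dose_tbl[[d]])
  fill <- function(day, drug, class, dose, supply = 30L) {
    data.frame(day = as.integer(day), drug = drug, class = class,
               dose = dose, supply = as.integer(supply),
               stringsAsFactors = FALSE)
  }
  monthly <- function(start, n, drug, dose, supply = 30L) {
    fill(start + 30L * (seq_len(n) - 1L), drug, "antidepressant", dose, supply)
  }
  A <- ads[1]; B <- ads[2]; C <- ads[3]
  dA <- amin(A) * sample(c(1, 1.5, 2), 1)
  dB <- amin(B) * sample(c(1, 1.5, 2), 1)
  dC <- amin(C) * sample(c(1, 1.5, 2), 1)
  switch(template,
    # --- treatment-resistant trajectories (3 lines, first 2 adequate) ----
    switch_switch = {
      gA <- sample(35:170, 1); nA <- max(1L, gA %/% 30L)
      gB <- sample(35:170, 1); nB <- max(1L, gB %/% 30L)
      rbind(monthly(0L, nA, A, dA),
            monthly(gA, nB, B, dB),
            monthly(gA + gB, 3L, C, dC))
    },
    switch_augment = {
      gA <- sample(35:170, 1); nA <- max(1L, gA %/% 30L)
      aday <- sample(14:60, 1)   # day (aday + 1) of the B regimen, >= Day 15
      rbind(monthly(0L, nA, A, dA),
            monthly(gA, 4L, B, dB),
            fill(gA + aday + 30L * (0:1), aug$drug_name, aug$drug_class,
                 NA_real_))
    },
    augment_switch = {
      a1 <- sample(14:45, 1)     # Day >= 15 of line 1, under active A supply
      g2 <- sample(29:170, 1)
      rbind(monthly(0L, 2L, A, dA),
            fill(a1, aug$drug_name, aug$drug_class, NA_real_),
            monthly(a1 + g2, 3L, B, dB))
    },
    # --- non-resistant trajectories --------------------------------------
    single_line = monthly(0L, 4L, A, dA),
    two_lines = {
      gA <- sample(35:170, 1); nA <- max(1L, gA %/% 30L)
      rbind(monthly(0L, nA, A, dA), monthly(gA, 3L, B, dB))
    },
    gap_short = {
      # 14-day index supply, second drug at day 16..27: no overlap, gap < 29
      # => not a qualifying failure; the line restarts on drug B.
      g <- sample(16:27, 1); gB <- sample(35:90, 1)
      rbind(fill(0L, A, "antidepressant", dA, 14L),
            monthly(g, max(1L, gB %/% 30L), B, dB),
            monthly(g + gB, 2L, C, dC))
    },
    gap_long = {
      # start-to-start gap > 180 with supply gap <= 180: same episode, no
      # qualifying failure; line restarts on drug B.
      g <- sample(185:250, 1)
      rbind(monthly(0L, 3L, A, dA), monthly(g, 2L, B, dB))
    },
    dose_low = {
      # resistant-shaped chain but first line at half the minimum dose
      gA <- sample(35:170, 1); nA <- max(1L, gA %/% 30L)
      aday <- sample(14:60, 1)
      rbind(monthly(0L, nA, A, amin(A) / 2),
            monthly(gA, 4L, B, dB),
            fill(gA + aday + 30L * (0:1), aug$drug_name, aug$drug_class,
                 NA_real_))
    },
    stopf("unknown template '%s'", template))
}

#' Generate a synthetic claims bundle
#'
#' Builds a complete administrative-claims world (patients, pharmacy claims,
#' medical claims, enrollment spells) with known per-patient ground truth.
#' Pharmacy histories are assembled from parameterized templates (switch day,
#' augmentation day, dose, number of fills) so that each patient either
#' satisfies the treatment-resistance definition exactly or fails it in one
#' targeted way (too-short gap, too-long gap, inadequate dose, fewer than 3
#' regimens). Annual total costs are drawn per patient-year from a gamma
#' distribution (mean multiplied by `cost_effect_ratio` for resistant-arm
#' follow-up years) and distributed across that year's claims; outpatient
#' visit counts are negative-binomial with mean multiplied by
#' `utilization_effect_ratio`.
#'
#' @param config a [simulation_config()].
#' @return object of class `claims_bundle`: list with `patients`,
#'   `pharmacy_claims`, `medical_claims`, `enrollment`, `ground_truth`
#'   data.frames and the `config`.
#' @export
generate_claims <- function(config) {
  if (!inherits(config, "simulation_config"))
    stopf("'config' must be a simulation_config object")
  empty <- empty_bundle(config)
  if (config$n_patients == 0L) return(empty)

  dose_tbl <- default_dose_table()
  ad_names <- names(dose_tbl)
  augs <- generator_augmentation_drugs()
  elix_map <- default_elixhauser_map()
  elix_cats <- setdiff(names(elix_map), "psychoses")
  flag_codes <- c(anxiety = "30000", personality_disorder = "30183",
                  substance_abuse = "30390", ptsd = "30981")
  flag_probs <- c(anxiety = 0.25, personality_disorder = 0.010,
                  substance_abuse = 0.030, ptsd = 0.015)
  dx_codes <- list("296" = c("29622", "29632"), "300" = "3004",
                   "309" = c("3090", "3091"), "311" = "311")
  dx_weights <- c(0.42, 0.14, 0.03, 0.41)

  with_seed(config$seed, {
    n <- config$n_patients
    id <- sprintf("P%06d", seq_len(n))
    win_len <- as.integer(config$study_window[2] - config$study_window[1]) + 1L
    index_date <- config$study_window[1] + sample.int(win_len, n, TRUE) - 1L
    age <- sample(18:63, n, TRUE)
    female <- stats::runif(n) < 0.62
    flags <- matrix(FALSE, n, length(flag_probs),
                    dimnames = list(NULL, names(flag_probs)))
    for (f in names(flag_probs)) flags[, f] <- stats::runif(n) < flag_probs[[f]]
    elix_n <- pmin(stats::rpois(n, 1.5), 8L)

    frac <- config$trd_trajectory_fraction
    trd <- if (frac <= 0) rep(FALSE, n) else if (frac >= 1) rep(TRUE, n) else {
      eta <- stats::qlogis(frac) +
        0.35 * (flags[, "anxiety"] - flag_probs[["anxiety"]]) +
        0.80 * (flags[, "ptsd"] - flag_probs[["ptsd"]]) +
        0.30 * (flags[, "substance_abuse"] - flag_probs[["substance_abuse"]]) -
        0.012 * (age - 40.5) +
        0.15 * (female - 0.62)
      stats::runif(n) < stats::plogis(eta)
    }
    template <- character(n)
    template[trd] <- sample(c("switch_switch", "switch_augment",
                              "augment_switch"), sum(trd), TRUE,
                            prob = c(0.4, 0.4, 0.2))
    template[!trd] <- sample(c("single_line", "two_lines", "gap_short",
                               "gap_long", "dose_low"), sum(!trd), TRUE,
                             prob = c(0.35, 0.30, 0.15, 0.10, 0.10))
    death <- stats::runif(n) < config$death_fraction
    disenroll <- stats::runif(n) < config$disenroll_fraction

    # birth date such that completed age at index equals `age`
    birth_date <- index_date - (ceiling(365.25 * age) +
                                sample.int(364L, n, TRUE) - 1L)

    size <- 1 / config$visit_dispersion
    share <- config$patient_cost_share
    pl <- vector("list", n); ml <- vector("list", n)
    enr <- vector("list", n); death_date <- rep(as.Date(NA), n)

    for (i in seq_len(n)) {
      ads <- sample(ad_names, 3L)
      aug <- augs[sample.int(nrow(augs), 1L), ]
      ph <- template_pharmacy(template[i], ads, aug, dose_tbl)

      # death only after the scripted pharmacy history has fully played out
      ddy <- NA_integer_
      if (death[i]) {
        lo <- max(400L, max(ph$day + ph$supply) + 40L)
        if (lo <= 720L) ddy <- sample(lo:720L, 1L)
      }

      # baseline medical claims: index diagnosis + comorbidity codes
      dx_cat <- sample(names(dx_codes), 1L, prob = dx_weights)
      dx_code <- sample(dx_codes[[dx_cat]], 1L)
      md_day <- -sample(1:10, 1L)
      m <- list(day = md_day, los = 1L, setting = "outpatient",
                icd = dx_code, proc = "")
      base_codes <- character(0)
      for (f in names(flag_codes)) if (flags[i, f])
        base_codes <- c(base_codes, flag_codes[[f]])
      if (elix_n[i] > 0) {
        cats <- sample(elix_cats, elix_n[i])
        base_codes <- c(base_codes,
                        vapply(cats, function(cc) paste0(elix_map[[cc]][1], "1"),
                               character(1)))
      }
      if (length(base_codes)) {
        m$day <- c(m$day, -sample(20:360, length(base_codes), TRUE))
        m$los <- c(m$los, rep(1L, length(base_codes)))
        m$setting <- c(m$setting, rep("outpatient", length(base_codes)))
        m$icd <- c(m$icd, base_codes)
        m$proc <- c(m$proc, rep("", length(base_codes)))
      }

      # per-year utilization
      yr_rng <- list(`0` = c(-360L, -11L), `1` = c(1L, 360L),
                     `2` = c(366L, 725L))
      for (y in 0:2) {
        mu <- switch(as.character(y),
                     `0` = config$visit_mean,
                     `1` = config$visit_mean *
                       if (trd[i]) config$utilization_effect_ratio else 1,
                     `2` = config$visit_mean * config$year2_visit_decay *
                       if (trd[i]) config$utilization_effect_ratio else 1)
        v <- stats::rnbinom(1L, size = size, mu = mu)
        rng <- yr_rng[[as.character(y)]]
        if (v > 0) {
          m$day <- c(m$day, sample(rng[1]:rng[2], v, TRUE))
          m$los <- c(m$los, rep(1L, v))
          m$setting <- c(m$setting, rep("outpatient", v))
          m$icd <- c(m$icd, rep("4659", v))
          m$proc <- c(m$proc, rep("", v))
        }
        p_ed <- if (y == 0 || !trd[i]) config$ed_base_prob else
          stats::plogis(stats::qlogis(config$ed_base_prob) +
                        log(config$ed_effect_or[y]))
        if (stats::runif(1) < p_ed) {
          m$day <- c(m$day, sample(rng[1]:rng[2], 1L))
          m$los <- c(m$los, 1L); m$setting <- c(m$setting, "ed")
          m$icd <- c(m$icd, "78650"); m$proc <- c(m$proc, "")
        }
        p_h <- if (y == 0 || !trd[i]) config$hosp_base_prob else
          stats::plogis(stats::qlogis(config$hosp_base_prob) +
                        log(config$hosp_effect_or[y]))
        if (stats::runif(1) < p_h) {
          los <- 1L + stats::rpois(1L, 3)
          st <- sample(rng[1]:(rng[2] - los), 1L)
          m$day <- c(m$day, st); m$los <- c(m$los, los)
          m$setting <- c(m$setting, "inpatient")
          m$icd <- c(m$icd, "486"); m$proc <- c(m$proc, "")
        }
      }

      med <- data.frame(day = as.integer(m$day), los = as.integer(m$los),
                        setting = m$setting, icd = m$icd, proc = m$proc,
                        stringsAsFactors = FALSE)

      # truncate at death / disenrollment
      end_day <- 770L
      if (!is.na(ddy)) { end_day <- ddy; death_date[i] <- index_date[i] + ddy }
      if (disenroll[i]) end_day <- min(end_day, 300L)
      med <- med[med$day <= end_day, , drop = FALSE]
      ph <- ph[ph$day <= end_day, , drop = FALSE]

      # guarantee each follow-up year carries at least one claim so annual
      # cost totals have a carrier
      for (y in 1:2) {
        rng <- yr_rng[[as.character(y)]]
        if (rng[1] > end_day) next
        has <- any(med$day >= (rng[1] - 1L) & med$day <= rng[2]) ||
          any(ph$day >= (rng[1] - 1L) & ph$day <= rng[2])
        if (!has) {
          med <- rbind(med, data.frame(day = rng[1], los = 1L,
                                       setting = "outpatient", icd = "4659",
                                       proc = "", stringsAsFactors = FALSE))
        }
      }

      # annual cost totals, distributed over the year's claims
      med$payer <- 0; med$patient <- 0
      ph$payer <- 0; ph$patient <- 0
      yr_of <- function(d) ifelse(d < 0L, 0L, ifelse(d <= 364L, 1L, 2L))
      med_yr <- yr_of(med$day); ph_yr <- yr_of(ph$day)
      for (y in 0:2) {
        mi <- which(med_yr == y); pi <- which(ph_yr == y)
        if (!length(mi) && !length(pi)) next
        mean_y <- config$baseline_cost_mean *
          if (y > 0 && trd[i]) config$cost_effect_ratio else 1
        tot <- stats::rgamma(1L, shape = config$cost_shape,
                             rate = config$cost_shape / mean_y)
        w_m <- if (length(mi))
          ifelse(med$setting[mi] == "inpatient", 8 * med$los[mi],
                 ifelse(med$setting[mi] == "ed", 3, 1)) else numeric(0)
        w_p <- rep(0.6, length(pi))
        w <- c(w_m, w_p); w <- w / sum(w)
        cost <- tot * w
        k <- length(mi)
        if (k) {
          med$payer[mi] <- round(cost[seq_len(k)] * (1 - share), 2)
          med$patient[mi] <- round(cost[seq_len(k)] * share, 2)
        }
        if (length(pi)) {
          med_part <- if (k) cost[-seq_len(k)] else cost
          ph$payer[pi] <- round(med_part * (1 - share), 2)
          ph$patient[pi] <- round(med_part * share, 2)
        }
      }

      pl[[i]] <- data.frame(
        patient_id = id[i],
        dispense_date = index_date[i] + ph$day,
        drug_name = ph$drug, drug_class = ph$class,
        daily_dose = ph$dose, days_supply = ph$supply,
        payer_cost = ph$payer, patient_cost = ph$patient,
        stringsAsFactors = FALSE)
      ml[[i]] <- data.frame(
        patient_id = id[i],
        service_start = index_date[i] + med$day,
        service_end = index_date[i] + med$day + med$los - 1L,
        setting = med$setting, icd_codes = med$icd,
        procedure_codes = med$proc,
        payer_cost = med$payer, patient_cost = med$patient,
        stringsAsFactors = FALSE)
      enr[[i]] <- data.frame(
        patient_id = id[i],
        start = index_date[i] - 420L,
        end = index_date[i] + end_day,
        has_pharmacy = TRUE, has_medical = TRUE, stringsAsFactors = FALSE)
    }

    bundle <- list(
      patients = data.frame(patient_id = id, birth_date = birth_date,
                            sex = ifelse(female, "female", "male"),
                            death_date = death_date, stringsAsFactors = FALSE),
      pharmacy_claims = do.call(rbind, pl),
      medical_claims = do.call(rbind, ml),
      enrollment = do.call(rbind, enr),
      ground_truth = data.frame(
        patient_id = id, template = template, trd_true = trd,
        index_date = index_date,
        cost_effect_ratio = ifelse(trd, config$cost_effect_ratio, 1),
        utilization_effect_ratio = ifelse(trd, config$utilization_effect_ratio, 1),
        died = !is.na(death_date), disenrolled = disenroll,
        stringsAsFactors = FALSE),
      config = config)
    rownames(bundle$pharmacy_claims) <- NULL
    rownames(bundle$medical_claims) <- NULL
    rownames(bundle$enrollment) <- NULL
    class(bundle) <- "claims_bundle"
    bundle
  })
}

empty_bundle <- function(config) {
  b <- list(
    patients = data.frame(patient_id = character(), birth_date = as.Date(character()),
                          sex = character(), death_date = as.Date(character()),
                          stringsAsFactors = FALSE),
    pharmacy_claims = data.frame(patient_id = character(),
                                 dispense_date = as.Date(character()),
                                 drug_name = character(), drug_class = character(),
                                 daily_dose = numeric(), days_supply = integer(),
                                 payer_cost = numeric(), patient_cost = numeric(),
                                 stringsAsFactors = FALSE),
    medical_claims = data.frame(patient_id = character(),
                                service_start = as.Date(character()),
                                service_end = as.Date(character()),
                                setting = character(), icd_codes = character(),
                                procedure_codes = character(),
                                payer_cost = numeric(), patient_cost = numeric(),
                                stringsAsFactors = FALSE),
    enrollment = data.frame(patient_id = character(), start = as.Date(character()),
                            end = as.Date(character()), has_pharmacy = logical(),
                            has_medical = logical(), stringsAsFactors = FALSE),
    ground_truth = data.frame(patient_id = character(), template = character(),
                              trd_true = logical(), index_date = as.Date(character()),
                              cost_effect_ratio = numeric(),
                              utilization_effect_ratio = numeric(),
                              died = logical(), disenrolled = logical(),
                              stringsAsFactors = FALSE),
    config = config)
  class(b) <- "claims_bundle"
  b
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Synthetic claims bundle\n")
  cat(sprintf("  patients:        %d\n", nrow(x$patients)))
  cat(sprintf("  pharmacy claims: %d\n", nrow(x$pharmacy_claims)))
  cat(sprintf("  medical claims:  %d\n", nrow(x$medical_claims)))
  cat(sprintf("  enrollment:      %d spells\n", nrow(x$enrollment)))
  if (nrow(x$ground_truth))
    cat(sprintf("  scripted resistant fraction: %.3f\n",
                mean(x$ground_truth$trd_true)))
  invisible(x)
}

bundle_schemas <- function() {
  list(
    patients = c(patient_id = "character", birth_date = "Date",
                 sex = "character", death_date = "Date"),
    pharmacy_claims = c(patient_id = "character", dispense_date = "Date",
                        drug_name = "character", drug_class = "character",
                        daily_dose = "numeric", days_supply = "integer",
                        payer_cost = "numeric", patient_cost = "numeric"),
    medical_claims = c(patient_id = "character", service_start = "Date",
                       service_end = "Date", setting = "character",
                       icd_codes = "character", procedure_codes = "character",
                       payer_cost = "numeric", patient_cost = "numeric"),
    enrollment = c(patient_id = "character", start = "Date", end = "Date",
                   has_pharmacy = "logical", has_medical = "logical"),
    ground_truth = c(patient_id = "character", template = "character",
                     trd_true = "logical", index_date = "Date",
                     cost_effect_ratio = "numeric",
                     utilization_effect_ratio = "numeric",
                     died = "logical", disenrolled = "logical"))
}

#' Write a claims bundle to a directory of CSV tables
#'
#' One RFC 4180 CSV per table (ISO-8601 dates) plus a JSON manifest listing
#' files, row counts and a hash of the generating configuration. The schema
#' is validated before anything is written, so a violation never leaves a
#' partial bundle behind.
#'
#' @param bundle a `claims_bundle`.
#' @param directory output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
write_bundle <- function(bundle, directory) {
  if (!inherits(bundle, "claims_bundle")) stopf("'bundle' must be a claims_bundle")
  schemas <- bundle_schemas()
  for (tb in names(schemas)) {
    df <- bundle[[tb]]
    if (!is.data.frame(df)) stopf("bundle table '%s' missing", tb)
    missing <- setdiff(names(schemas[[tb]]), names(df))
    if (length(missing))
      stopf("schema violation in '%s': missing column(s) %s", tb,
            paste(missing, collapse = ", "))
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (tb in names(schemas)) {
    df <- bundle[[tb]][, names(schemas[[tb]]), drop = FALSE]
    path <- file.path(directory, paste0(tb, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files[[tb]] <- list(file = paste0(tb, ".csv"), rows = nrow(df))
  }
  cfg <- bundle$config
  cfg_json <- jsonlite::toJSON(unclass_config(cfg), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(tables = files,
                   config = jsonlite::fromJSON(cfg_json),
                   config_hash = unname(tools::md5sum(tf)))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$study_window <- format(out$study_window)
  out
}

#' Read a claims bundle written by [write_bundle()]
#'
#' @param directory directory containing the CSV tables and manifest.
#' @return a `claims_bundle`.
#' @export
read_bundle <- function(directory) {
  schemas <- bundle_schemas()
  out <- list()
  for (tb in names(schemas)) {
    path <- file.path(directory, paste0(tb, ".csv"))
    if (!file.exists(path)) stopf("missing bundle table file '%s'", path)
    sch <- schemas[[tb]]
    cls <- ifelse(sch == "Date", "character", sch)
    df <- utils::read.csv(path, colClasses = unname(cls),
                          stringsAsFactors = FALSE)
    for (col in names(sch)[sch == "Date"]) {
      df[[col]] <- if (nrow(df) == 0L) as.Date(character()) else
        as.Date(ifelse(df[[col]] == "", NA, df[[col]]))
    }
    out[[tb]] <- df
  }
  mf <- file.path(directory, "manifest.json")
  cfg <- NULL
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf, simplifyVector = TRUE)
    cm <- m$config
    cfg <- simulation_config(
      n_patients = cm$n_patients,
      trd_trajectory_fraction = cm$trd_trajectory_fraction,
      cost_effect_ratio = cm$cost_effect_ratio,
      utilization_effect_ratio = cm$utilization_effect_ratio,
      baseline_cost_mean = cm$baseline_cost_mean,
      cost_shape = cm$cost_shape, visit_mean = cm$visit_mean,
      visit_dispersion = cm$visit_dispersion,
      year2_visit_decay = cm$year2_visit_decay,
      ed_base_prob = cm$ed_base_prob, hosp_base_prob = cm$hosp_base_prob,
      ed_effect_or = cm$ed_effect_or, hosp_effect_or = cm$hosp_effect_or,
      death_fraction = cm$death_fraction,
      disenroll_fraction = cm$disenroll_fraction,
      patient_cost_share = cm$patient_cost_share, seed = cm$seed,
      study_window = as.Date(cm$study_window))
  }
  out$config <- cfg
  class(out) <- "claims_bundle"
  out
}
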