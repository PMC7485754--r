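#' Find the index date
#'
#' The index date anchoring a patient's study windows is the date of their
#' first antidepressant dispensing inside the configured index window.
#'
#' @param pharmacy_claims pharmacy claims for one patient.
#' @param study_window two dates; defaults to the window in [study_params()].
#' @return a `Date`, or `NA` if no qualifying dispensing exists.
#' @export
find_index_date <- function(pharmacy_claims,
                            study_window = study_params()$index_window) {
  d <- as.Date(pharmacy_claims$dispense_date)
  keep <- pharmacy_claims$drug_class == "antidepressant" &
    d >= study_window[1] & d <= study_window[2]
  if (!any(keep)) return(as.Date(NA))
  min(d[keep])
}

#' Check cohort eligibility
#'
#' Applies the inclusion rules relative to a known index date and reports
#' every failed criterion: age 18-63 at index; a pre-index washout free of
#' depression-treatment claims (any antidepressant or augmentation-class
#' dispensing, ECT/TMS, or psychotherapy procedure); a qualifying depression
#' diagnosis within the diagnosis window of the index date; at least two
#' antidepressant dispensings with a refill gap no larger than
#' `refill_gap_days` after the index fill's supply ends; and continuous
#' enrollment with both benefits over baseline plus follow-up (required only
#' up to the death date for decedents).
#'
#' @param patient one-row data.frame (or list) with `patient_id`,
#'   `birth_date`, optional `death_date`.
#' @param pharmacy_claims,medical_claims,enrollment this patient's records.
#' @param index_date the index date.
#' @param params a [study_params()].
#' @param code_lists a [default_code_lists()].
#' @return list with `eligible` (logical) and `reasons` (character vector of
#'   failed criteria, in check order).
#' @export
check_eligibility <- function(patient, pharmacy_claims, medical_claims,
                              enrollment, index_date,
                              params = study_params(),
                              code_lists = default_code_lists()) {
  pid <- patient$patient_id
  for (df in list(pharmacy_claims, medical_claims, enrollment)) {
    if (nrow(df) && any(df$patient_id != pid))
      stopf("claims reference a patient other than '%s'", pid)
  }
  index_date <- as.Date(index_date)
  if (is.na(index_date)) stopf("index_date must be defined")
  reasons <- character(0)

  age <- age_at(patient$birth_date, index_date)
  if (age < 18 || age > 63) reasons <- c(reasons, "age")

  # washout: any depression treatment in the `washout_days` before index
  w0 <- index_date - params$washout_days
  pd <- as.Date(pharmacy_claims$dispense_date)
  rx_classes <- c("antidepressant", code_lists$augmentation_classes)
  rx_hit <- pharmacy_claims$drug_class %in% rx_classes &
    pd >= w0 & pd < index_date
  proc_list <- c(code_lists$exclusion_procedures,
                 code_lists$psychotherapy_procedures)
  ms <- as.Date(medical_claims$service_start)
  proc_hit <- claims_match_codes(medical_claims$procedure_codes, proc_list) &
    ms >= w0 & ms < index_date
  if (any(rx_hit) || any(proc_hit)) reasons <- c(reasons, "washout")

  # qualifying depression diagnosis near index
  dx <- claims_match_codes(medical_claims$icd_codes, code_lists$mdd_prefixes,
                           code_lists$mdd_exclude)
  near <- abs(as.integer(ms - index_date)) <= params$diagnosis_window_days
  if (!any(dx & near)) reasons <- c(reasons, "diagnosis_window")

  # at least two antidepressant dispensings with a bounded refill gap
  ad <- pharmacy_claims[pharmacy_claims$drug_class == "antidepressant" &
                          pd >= index_date, , drop = FALSE]
  ad <- ad[order(as.Date(ad$dispense_date)), , drop = FALSE]
  ok_refill <- nrow(ad) >= 2L &&
    as.integer(as.Date(ad$dispense_date[2]) - as.Date(ad$dispense_date[1])) <=
      ad$days_supply[1] + params$refill_gap_days
  if (!ok_refill) reasons <- c(reasons, "refill_gap")

  # continuous enrollment with both benefits
  need_end <- index_date + params$followup_days
  dd <- patient$death_date %||% as.Date(NA)
  if (!is.na(dd)) need_end <- min(need_end, as.Date(dd))
  need_start <- index_date - params$baseline_days
  sp <- enrollment[enrollment$has_pharmacy & enrollment$has_medical, ,
                   drop = FALSE]
  iv <- merge_intervals(sp$start, sp$end)
  covered <- any(iv$start <= need_start & iv$end >= need_end)
  if (!covered) reasons <- c(reasons, "enrollment")

  list(eligible = length(reasons) == 0L, reasons = reasons)
}

#' Apply exclusion rules
#'
#' A patient is excluded if an exclusion diagnosis (psychosis, schizophrenia,
#' mania, bipolar disorder, dementia) appears anywhere in their record at any
#' time, or if an exclusion drug class (lithium, thyroid hormone,
#' antipsychotic, anticonvulsant mood stabilizer) or procedure (ECT, TMS)
#' appears during the washout window before the index date.
#'
#' @inheritParams check_eligibility
#' @return list with `excluded` (logical) and `reasons`.
#' @export
apply_exclusions <- function(patient, pharmacy_claims, medical_claims,
                             code_lists = default_code_lists(), index_date,
                             params = study_params()) {
  index_date <- as.Date(index_date)
  if (is.na(index_date)) stopf("index_date must be defined")
  reasons <- character(0)
  if (any(claims_match_codes(medical_claims$icd_codes,
                             code_lists$exclusion_diagnosis_codes)))
    reasons <- c(reasons, "exclusion_diagnosis")
  w0 <- index_date - params$washout_days
  pd <- as.Date(pharmacy_claims$dispense_date)
  if (any(pharmacy_claims$drug_class %in% code_lists$exclusion_drug_classes &
          pd >= w0 & pd < index_date))
    reasons <- c(reasons, "exclusion_drug")
  ms <- as.Date(medical_claims$service_start)
  if (any(claims_match_codes(medical_claims$procedure_codes,
                             code_lists$exclusion_procedures) &
          ms >= w0 & ms < index_date))
    reasons <- c(reasons, "exclusion_procedure")
  list(excluded = length(reasons) > 0L, reasons = reasons)
}

# Diagnosis-category label for a normalized MDD code.
dx_category <- function(code) {
  if (startsWith(code, "296")) "296.X"
  else if (startsWith(code, "3004")) "300.X"
  else if (startsWith(code, "309")) "309.X"
  else if (startsWith(code, "311")) "311.X"
  else NA_character_
}

#' Extract baseline covariates for one cohort record
#'
#' Computes the covariate row used for the propensity model and balance
#' tables: age group (18-24, 25-34, 35-44, 45-54, 55-63), sex, index year,
#' diagnosis category (from the qualifying code on the claim nearest the
#' index date, ties broken 296.X > 300.X > 309.X > 311.X), four baseline
#' comorbidity flags, and the Elixhauser score over the baseline window.
#'
#' @param record list/one-row data.frame with `patient_id`, `index_date`,
#'   `age_at_index`, `sex`.
#' @param medical_claims this patient's medical claims.
#' @param code_lists a [default_code_lists()].
#' @param elixhauser_map a 30-category map, see [default_elixhauser_map()].
#' @param params a [study_params()].
#' @return one-row data.frame of covariates.
#' @export
extract_baseline_covariates <- function(record, medical_claims,
                                        code_lists = default_code_lists(),
                                        elixhauser_map = default_elixhauser_map(),
                                        params = study_params()) {
  age <- record$age_at_index
  if (age < 18 || age > 63) stopf("age %s outside 18-63: upstream contract violated", age)
  idx <- as.Date(record$index_date)
  ms <- as.Date(medical_claims$service_start)
  off <- as.integer(ms - idx)

  # diagnosis category: nearest qualifying claim, category-priority ties
  cat_priority <- c("296.X" = 1, "300.X" = 2, "309.X" = 3, "311.X" = 4)
  dxrows <- which(claims_match_codes(medical_claims$icd_codes,
                                     code_lists$mdd_prefixes,
                                     code_lists$mdd_exclude) &
                    abs(off) <= params$diagnosis_window_days)
  diag_cat <- NA_character_
  if (length(dxrows)) {
    cand <- do.call(rbind, lapply(dxrows, function(i) {
      codes <- split_codes(medical_claims$icd_codes[i])[[1]]
      codes <- codes[code_matches(codes, code_lists$mdd_prefixes,
                                  code_lists$mdd_exclude)]
      cats <- vapply(codes, dx_category, character(1))
      data.frame(dist = abs(off[i]), cat = cats, stringsAsFactors = FALSE)
    }))
    cand <- cand[!is.na(cand$cat), , drop = FALSE]
    cand <- cand[order(cand$dist, cat_priority[cand$cat]), , drop = FALSE]
    if (nrow(cand)) diag_cat <- cand$cat[1]
  }

  in_base <- off >= -params$baseline_days & off <= -1L
  base_claims <- medical_claims[in_base, , drop = FALSE]
  flag <- function(prefixes)
    any(claims_match_codes(base_claims$icd_codes, prefixes))
  bf <- code_lists$baseline_flags
  data.frame(
    patient_id = record$patient_id,
    age_at_index = age,
    age_group = cut(age, breaks = c(17, 24, 34, 44, 54, 63),
                    labels = c("18-24", "25-34", "35-44", "45-54", "55-63")),
    sex = record$sex,
    index_year = as.integer(format(idx, "%Y")),
    diagnosis_category = diag_cat,
    anxiety = flag(bf$anxiety),
    personality_disorder = flag(bf$personality_disorder),
    substance_abuse = flag(bf$substance_abuse),
    ptsd = flag(bf$ptsd),
    elixhauser = compute_elixhauser(base_claims, elixhauser_map),
    stringsAsFactors = FALSE)
}

#' Build the study cohort
#'
#' Applies index-date identification, eligibility and exclusion rules to a
#' claims bundle (or a named list of claims tables) and emits one cohort
#' record per eligible patient together with a disposition count. Every
#' patient is counted exactly once in the disposition: under `no_index`,
#' under the first failed eligibility criterion, under the first exclusion
#' reason, or under `eligible`.
#'
#' @param data a `claims_bundle` or list with `patients`, `pharmacy_claims`,
#'   `medical_claims`, `enrollment`.
#' @param params a [study_params()].
#' @param code_lists a [default_code_lists()].
#' @param elixhauser_map see [default_elixhauser_map()].
#' @return object of class `trd_cohort`: list with `cohort` (one row per
#'   eligible patient) and `disposition` (named integer vector).
#' @export
build_cohort <- function(data, params = study_params(),
                         code_lists = default_code_lists(),
                         elixhauser_map = default_elixhauser_map()) {
  patients <- data$patients
  known <- patients$patient_id
  for (tb in c("pharmacy_claims", "medical_claims", "enrollment")) {
    bad <- setdiff(unique(data[[tb]]$patient_id), known)
    if (length(bad))
      stopf("%s references unknown patient(s): %s", tb,
            paste(utils::head(bad, 3), collapse = ", "))
  }
  sp_ph <- split(data$pharmacy_claims,
                 factor(data$pharmacy_claims$patient_id, levels = known))
  sp_md <- split(data$medical_claims,
                 factor(data$medical_claims$patient_id, levels = known))
  sp_en <- split(data$enrollment,
                 factor(data$enrollment$patient_id, levels = known))

  rows <- vector("list", nrow(patients))
  disp <- character(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pat <- patients[i, ]
    ph <- sp_ph[[i]]; md <- sp_md[[i]]; en <- sp_en[[i]]
    idx <- find_index_date(ph, params$index_window)
    if (is.na(idx)) { disp[i] <- "no_index"; next }
    el <- check_eligibility(pat, ph, md, en, idx, params, code_lists)
    if (!el$eligible) { disp[i] <- paste0("ineligible_", el$reasons[1]); next }
    ex <- apply_exclusions(pat, ph, md, code_lists, idx, params)
    if (ex$excluded) { disp[i] <- ex$reasons[1]; next }
    disp[i] <- "eligible"
    rec <- list(patient_id = pat$patient_id, index_date = idx,
                age_at_index = age_at(pat$birth_date, idx), sex = pat$sex)
    cov <- extract_baseline_covariates(rec, md, code_lists, elixhauser_map,
                                       params)
    cov$index_date <- idx
    cov$death_date <- as.Date(pat$death_date %||% NA)
    rows[[i]] <- cov
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cohort)) {
    cohort <- data.frame(patient_id = character(0))
  }
  rownames(cohort) <- NULL
  out <- list(cohort = cohort, disposition = table(disp))
  class(out) <- "trd_cohort"
  out
}

#' @export
print.trd_cohort <- function(x, ...) {
  cat("Claims cohort:", nrow(x$cohort), "eligible patients\n")
  cat("Disposition:\n")
  print(x$disposition)
  invisible(x)
}
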