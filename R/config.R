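#' Study design constants
#'
#' Day-exact study-window parameters used throughout the pipeline. Months are
#' implemented as fixed day counts (6 months = 183 days, 12 months = 365,
#' 24 months = 730) so results do not depend on calendar-month arithmetic;
#' every constant can be overridden here.
#'
#' @param index_window two dates: first antidepressant dispensings inside this
#'   window anchor the cohort. Default 2013-01-01 to 2014-09-30; pass
#'   `as.Date(c("2013-01-01","2013-09-30"))` for the narrower variant.
#' @param washout_days pre-index interval (days) that must be free of
#'   depression-treatment claims.
#' @param baseline_days length of the pre-index baseline period.
#' @param followup_days length of the post-index follow-up period.
#' @param diagnosis_window_days a qualifying depression diagnosis must fall
#'   within this many days of the index date (either side).
#' @param refill_gap_days maximum days between the end of the index fill's
#'   supply and the second antidepressant dispensing.
#' @param episode_gap_days a gap in antidepressant/augmentation supply longer
#'   than this ends the treatment episode.
#' @param switch_min_days,switch_max_days inclusive start-to-start gap window
#'   (days) in which introducing a non-overlapping second antidepressant marks
#'   the current drug as a failure.
#' @param augment_min_day earliest regimen day (start = Day 1) on which adding
#'   a second agent under active supply marks the regimen as failed.
#' @return named list of class `trd_params`.
#' @export
study_params <- function(index_window = as.Date(c("2013-01-01", "2014-09-30")),
                         washout_days = 183L,
                         baseline_days = 365L,
                         followup_days = 730L,
                         diagnosis_window_days = 30L,
                         refill_gap_days = 30L,
                         episode_gap_days = 180L,
                         switch_min_days = 29L,
                         switch_max_days = 180L,
                         augment_min_day = 15L) {
  p <- list(index_window = as.Date(index_window),
            washout_days = as.integer(washout_days),
            baseline_days = as.integer(baseline_days),
            followup_days = as.integer(followup_days),
            diagnosis_window_days = as.integer(diagnosis_window_days),
            refill_gap_days = as.integer(refill_gap_days),
            episode_gap_days = as.integer(episode_gap_days),
            switch_min_days = as.integer(switch_min_days),
            switch_max_days = as.integer(switch_max_days),
            augment_min_day = as.integer(augment_min_day))
  stopifnot(length(p$index_window) == 2L, p$index_window[1] <= p$index_window[2],
            p$switch_min_days <= p$switch_max_days, p$augment_min_day >= 2L)
  class(p) <- "trd_params"
  p
}

#' Diagnosis, drug-class and procedure code lists
#'
#' Configurable code sets driving inclusion, exclusion and baseline
#' covariates. Defaults: depression diagnoses are ICD-9 296.2x and 296.3x
#' (except 296.25 and 296.30), 300.4, 309.0, 309.1 and 311; exclusion
#' diagnoses cover psychosis, schizophrenia, mania, bipolar disorder and
#' dementia; exclusion drug classes are lithium, thyroid hormone,
#' antipsychotics and anticonvulsant-type mood stabilizers; exclusion
#' procedures are ECT and TMS. Matching is prefix-based on normalized
#' (dot-free) codes.
#'
#' @param mdd_prefixes,mdd_exclude prefixes defining a qualifying depression
#'   diagnosis, and sub-prefixes carved out of them.
#' @param exclusion_diagnosis_codes prefixes that exclude a patient when seen
#'   at any time.
#' @param exclusion_drug_classes dispensing classes that exclude a patient
#'   when seen in the pre-index washout.
#' @param exclusion_procedures,psychotherapy_procedures procedure codes; the
#'   former exclude in the washout, both count as depression treatment in the
#'   washout check.
#' @param augmentation_classes drug classes treated as augmentation agents.
#' @param baseline_flags named list of ICD prefixes for the four baseline
#'   comorbidity flags.
#' @return list of class `trd_code_lists`.
#' @export
default_code_lists <- function(
    mdd_prefixes = c("2962", "2963", "3004", "3090", "3091", "311"),
    mdd_exclude = c("29625", "29630"),
    exclusion_diagnosis_codes = c("290", "295", "2960", "2961", "2964",
                                  "2965", "2966", "2967", "2968", "297",
                                  "298", "F20", "F21", "F22", "F23", "F24",
                                  "F25", "F28", "F29", "F30", "F31"),
    exclusion_drug_classes = c("lithium", "thyroid_hormone", "antipsychotic",
                               "anticonvulsant"),
    exclusion_procedures = c("ECT", "TMS"),
    psychotherapy_procedures = c("90832", "90834", "90837"),
    augmentation_classes = c("anticonvulsant", "antipsychotic", "lithium",
                             "psychostimulant", "thyroid_hormone"),
    baseline_flags = list(anxiety = "3000",
                          personality_disorder = "301",
                          substance_abuse = c("303", "304", "305"),
                          ptsd = "30981")) {
  cl <- list(mdd_prefixes = mdd_prefixes, mdd_exclude = mdd_exclude,
             exclusion_diagnosis_codes = exclusion_diagnosis_codes,
             exclusion_drug_classes = exclusion_drug_classes,
             exclusion_procedures = exclusion_procedures,
             psychotherapy_procedures = psychotherapy_procedures,
             augmentation_classes = augmentation_classes,
             baseline_flags = baseline_flags)
  stopifnot(length(mdd_prefixes) > 0, length(exclusion_diagnosis_codes) > 0,
            length(baseline_flags) == 4L)
  class(cl) <- "trd_code_lists"
  cl
}

#' Minimum adequate daily doses for antidepressants
#'
#' Guideline-style minimum daily doses (mg/day) per canonical drug name.
#' These defaults are implementer-supplied working values in the spirit of
#' practice-guideline minimums; they are configuration, and any study should
#' review and override them for its own drug list.
#'
#' @return named numeric vector, mg/day.
#' @export
default_dose_table <- function() {
  c(citalopram   = 20,
    escitalopram = 10,
    fluoxetine   = 20,
    paroxetine   = 20,
    sertraline   = 50,
    fluvoxamine  = 100,
    venlafaxine  = 75,
    desvenlafaxine = 50,
    duloxetine   = 60,
    bupropion    = 300,
    mirtazapine  = 15,
    trazodone    = 150,
    nortriptyline = 50,
    amitriptyline = 75,
    vilazodone   = 20,
    vortioxetine = 10)
}

#' Elixhauser comorbidity category map
#'
#' A 30-category map from ICD-9 prefixes (dot-free) to Elixhauser comorbidity
#' categories, with combined hypertension. The prefix lists are simplified,
#' documented defaults: each category is represented by its most common
#' code stems, not the exhaustive published enumeration, and the map is
#' intended to be replaced with a site-validated version for real data.
#'
#' @return named list of 30 character vectors of code prefixes.
#' @export
default_elixhauser_map <- function() {
  list(
    congestive_heart_failure = c("428"),
    cardiac_arrhythmia       = c("426", "427"),
    valvular_disease         = c("394", "395", "396", "397", "424"),
    pulmonary_circulation    = c("415", "416", "417"),
    peripheral_vascular      = c("440", "441", "443"),
    hypertension             = c("401", "402", "403", "404", "405"),
    paralysis                = c("342", "343", "344"),
    other_neurological       = c("330", "331", "332", "333", "334", "335",
                                 "340", "341", "345"),
    chronic_pulmonary        = c("490", "491", "492", "493", "494", "495",
                                 "496"),
    diabetes_uncomplicated   = c("2500", "2501", "2502", "2503"),
    diabetes_complicated     = c("2504", "2505", "2506", "2507", "2508",
                                 "2509"),
    hypothyroidism           = c("240", "243", "244"),
    renal_failure            = c("585", "586"),
    liver_disease            = c("570", "571", "572", "573"),
    peptic_ulcer             = c("531", "532", "533", "534"),
    aids_hiv                 = c("042", "043", "044"),
    lymphoma                 = c("200", "201", "202"),
    metastatic_cancer        = c("196", "197", "198", "199"),
    solid_tumor              = c("150", "151", "152", "153", "154", "155",
                                 "157", "160", "161", "162", "163", "170",
                                 "171", "172", "174", "175", "180", "182",
                                 "183", "185", "186", "187", "188", "189",
                                 "190", "191", "193", "194"),
    rheumatoid_arthritis     = c("701", "710", "714", "720", "725"),
    coagulopathy             = c("286", "2871", "2873"),
    obesity                  = c("2780"),
    weight_loss              = c("260", "261", "262", "263"),
    fluid_electrolyte        = c("276"),
    blood_loss_anemia        = c("2800"),
    deficiency_anemia        = c("2801", "2808", "2809", "281"),
    alcohol_abuse            = c("2911", "2912", "2913", "2914", "2915",
                                 "3050"),
    drug_abuse               = c("292", "304", "3052", "3053", "3054",
                                 "3055"),
    psychoses                = c("295", "297", "298"),
    depression               = c("3004", "3011", "309", "311")
  )
}
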