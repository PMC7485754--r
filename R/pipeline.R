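#' Run the full claims analysis pipeline
#'
#' End-to-end seeded pipeline: generate (or accept) a claims bundle, build
#' the eligible cohort, classify treatment resistance, fit the propensity
#' model, match cases to controls (greedy, 1:`ratio`, caliper on the
#' probability scale), aggregate per-patient-year utilization and costs, and
#' fit the adjusted outcome models on the matched sample:
#' negative-binomial models for outpatient visits and hospital days,
#' repeated-measures logistic models for any ED visit and any
#' hospitalization, and gamma (plus linear-sensitivity and by-diagnosis
#' subgroup) models for total healthcare cost. Identical inputs and seeds
#' reproduce every number and report file exactly.
#'
#' @param data a [simulation_config()] (the bundle is generated) or an
#'   existing `claims_bundle`.
#' @param ratio,caliper matching parameters.
#' @param iterations bootstrap iterations for cost/count CIs.
#' @param seed seed for the bootstrap stage (bundle generation uses the
#'   config's own seed).
#' @param out_dir optional directory for [render_reports()] output.
#' @param inflation_table optional calendar-year cost multipliers.
#' @param dose_table,params,code_lists,elixhauser_map configuration objects.
#' @return object of class `trd_analysis`: list with `bundle`, `cohort`,
#'   `disposition`, `propensity`, `matched`, `balance`, `outcomes`
#'   (annual + baseline tables), `models`, `report_files`.
#' @export
run_trd_pipeline <- function(data, ratio = 4L, caliper = 0.02,
                             iterations = 200L, seed = 1L, out_dir = NULL,
                             inflation_table = NULL,
                             dose_table = default_dose_table(),
                             params = study_params(),
                             code_lists = default_code_lists(),
                             elixhauser_map = default_elixhauser_map()) {
  bundle <- if (inherits(data, "simulation_config")) generate_claims(data)
            else data
  cb <- build_cohort(bundle, params, code_lists, elixhauser_map)
  cohort <- classify_cohort(cb$cohort, bundle$pharmacy_claims, dose_table,
                            params, code_lists)
  if (!nrow(cohort) || length(unique(cohort$trd)) < 2L)
    stopf("cohort has no cases or no controls; cannot match")

  ps <- fit_propensity(cohort)
  m <- greedy_match(ps$scores, cohort$trd, ratio = ratio, caliper = caliper,
                    ids = cohort$patient_id)
  bal <- balance_table(cohort, m)
  matched_ids <- c(unique(m$matches$case_id), m$matches$control_id)
  mc <- cohort[cohort$patient_id %in% matched_ids, , drop = FALSE]

  idx <- mc[, c("patient_id", "index_date")]
  ann <- annualize_outcomes(bundle$medical_claims, bundle$pharmacy_claims,
                            idx, years = c(1L, 2L), inflation_table)
  base <- baseline_outcomes(bundle$medical_claims, bundle$pharmacy_claims,
                            idx, inflation_table)
  lab <- mc$trd[match(ann$patient_id, mc$patient_id)]
  blab <- match(ann$patient_id, base$patient_id)
  elix <- mc$elixhauser[match(ann$patient_id, mc$patient_id)]

  models <- list()
  util_rows <- list(); cost_rows <- list()
  sd_off <- 0L
  for (y in 1:2) {
    sel <- ann$follow_year == y
    models[[paste0("visits_y", y)]] <- fit_count_model(
      ann$outpatient_visits[sel], lab[sel],
      base$outpatient_visits[blab[sel]],
      iterations = iterations, seed = seed + sd_off)
    util_rows[[length(util_rows) + 1L]] <-
      model_result_row(models[[paste0("visits_y", y)]], "outpatient_visits", y)
    sd_off <- sd_off + 1L
    models[[paste0("los_y", y)]] <- fit_count_model(
      ann$hospital_los[sel], lab[sel], base$hospital_los[blab[sel]],
      iterations = iterations, seed = seed + sd_off)
    util_rows[[length(util_rows) + 1L]] <-
      model_result_row(models[[paste0("los_y", y)]], "hospital_los", y)
    sd_off <- sd_off + 1L
    models[[paste0("total_cost_y", y)]] <- fit_cost_model(
      ann$total_healthcare[sel], lab[sel], base$total_healthcare[blab[sel]],
      family = "gamma_log", iterations = iterations, seed = seed + sd_off)
    cost_rows[[length(cost_rows) + 1L]] <-
      model_result_row(models[[paste0("total_cost_y", y)]],
                       "total_healthcare", y)
    sd_off <- sd_off + 1L
  }
  for (oc in c("any_ed", "any_hospitalization")) {
    models[[oc]] <- fit_repeated_logistic(
      as.integer(ann[[oc]]), lab, ann$follow_year,
      as.integer(base[[oc]][blab]), elix, ann$patient_id)
    util_rows[[length(util_rows) + 1L]] <- or_result_rows(models[[oc]], oc)
  }
  sel1 <- ann$follow_year == 1
  models$total_cost_y1_linear <- fit_cost_model(
    ann$total_healthcare[sel1], lab[sel1],
    base$total_healthcare[blab[sel1]], family = "linear_normal",
    iterations = iterations, seed = seed + sd_off)
  cost_rows[[length(cost_rows) + 1L]] <-
    model_result_row(models$total_cost_y1_linear, "total_healthcare_linear", 1L)
  models$subgroups_y1 <- subgroup_costs_by_diagnosis(
    ann$total_healthcare[sel1], lab[sel1],
    base$total_healthcare[blab[sel1]],
    mc$diagnosis_category[match(ann$patient_id[sel1], mc$patient_id)])

  util_df <- do.call(rbind, util_rows)
  cost_df <- do.call(rbind, cost_rows)
  report_files <- NULL
  if (!is.null(out_dir))
    report_files <- render_reports(out_dir, bal, util_df, cost_df)

  out <- list(bundle = bundle, cohort = cohort,
              disposition = cb$disposition, propensity = ps, matched = m,
              balance = bal,
              outcomes = list(annual = ann, baseline = base),
              models = models, utilization_table = util_df,
              cost_table = cost_df, report_files = report_files)
  class(out) <- "trd_analysis"
  out
}

#' @export
print.trd_analysis <- function(x, ...) {
  cat("Treatment-resistant depression claims analysis\n")
  cat(sprintf("  cohort: %d eligible, %d resistant (%.1f%%)\n",
              nrow(x$cohort), sum(x$cohort$trd),
              100 * mean(x$cohort$trd)))
  cat(sprintf("  matched: %d cases : %d controls\n",
              length(unique(x$matched$matches$case_id)),
              nrow(x$matched$matches)))
  cat("\nUtilization:\n")
  print(x$utilization_table[, c("outcome", "year", "estimate", "ci_lower",
                                "ci_upper")], row.names = FALSE)
  cat("\nCosts:\n")
  print(x$cost_table[, c("outcome", "year", "estimate", "ci_lower",
                         "ci_upper")], row.names = FALSE)
  invisible(x)
}
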