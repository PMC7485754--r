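#' Classify a drug transition
#'
#' Implements the regimen-failure rule at the heart of the
#' treatment-resistance algorithm. Day numbering: the regimen start date is
#' Day 1, so a new drug starting on Day k has a start-to-start gap of k - 1
#' days. If the current regimen's supply does not cover the new drug's start
#' (switch pathway), the current drug is a failure when the gap is between
#' `switch_min_days` and `switch_max_days` inclusive (29-180 by default),
#' otherwise no failure. If supply does cover the start (augmentation
#' pathway), a new agent on Days 1-14 is part of the same combination
#' regimen, while one starting on Day `augment_min_day` (15) or later marks
#' the regimen as failed by augmentation.
#'
#' @param regimen_start date the current regimen started (Day 1).
#' @param prior_drug_coverage either a logical (is the new start covered by
#'   the current regimen's supply?) or a data.frame of covered intervals with
#'   `start`/`end` dates.
#' @param new_drug_start date the new drug starts.
#' @param params a [study_params()].
#' @return one of `"switch_failure"`, `"augmentation_failure"`,
#'   `"same_regimen"`, `"no_failure"`.
#' @export
classify_drug_transition <- function(regimen_start, prior_drug_coverage,
                                     new_drug_start,
                                     params = study_params()) {
  regimen_start <- as.Date(regimen_start)
  new_drug_start <- as.Date(new_drug_start)
  gap <- as.integer(new_drug_start - regimen_start)
  if (gap < 0) stopf("new_drug_start precedes regimen_start")
  covered <- if (is.logical(prior_drug_coverage)) {
    isTRUE(prior_drug_coverage)
  } else {
    any(as.Date(prior_drug_coverage$start) <= new_drug_start &
          as.Date(prior_drug_coverage$end) >= new_drug_start)
  }
  if (covered) {
    if (gap <= params$augment_min_day - 2L) "same_regimen"
    else "augmentation_failure"
  } else {
    if (gap >= params$switch_min_days && gap <= params$switch_max_days)
      "switch_failure"
    else "no_failure"
  }
}

# Supply-coverage intervals for the given drugs within a claims table.
coverage_intervals <- function(claims, drugs) {
  k <- claims[claims$drug_name %in% drugs, , drop = FALSE]
  if (!nrow(k)) return(data.frame(start = as.Date(character()),
                                  end = as.Date(character())))
  data.frame(start = as.Date(k$dispense_date),
             end = as.Date(k$dispense_date) + k$days_supply - 1L)
}

#' Build the treatment episode for one patient
#'
#' The current depression treatment episode is the maximal run of
#' antidepressant/augmentation supply starting at the index dispensing in
#' which consecutive covered intervals are separated by at most
#' `episode_gap_days` (180 by default, matching the switch-failure ceiling);
#' claims after the first larger gap belong to a later episode and are
#' dropped. Within the episode, therapy lines (regimens) are segmented by
#' running [classify_drug_transition()] over each new drug's first
#' dispensing:
#' \itemize{
#'   \item `same_regimen`: the drug joins the current combination;
#'   \item `switch_failure` / `augmentation_failure`: the current line is
#'     closed with that failure mode and the next line starts (an
#'     augmentation failure carries the current drugs into the new line);
#'   \item `no_failure` (a switch outside the qualifying window): the current
#'     line restarts on the new drug without a recorded failure, so only the
#'     final regimen can have `failure_mode = "none"`.
#' }
#' Augmentation-class drugs starting while no regimen drug is supplied
#' cannot anchor an antidepressant regimen and are ignored for sequencing.
#'
#' @param pharmacy_claims one patient's pharmacy claims.
#' @param index_date the index date; an antidepressant dispensing must exist
#'   on this date.
#' @param gap_days episode-ending supply gap, days.
#' @param params a [study_params()].
#' @param code_lists a [default_code_lists()].
#' @return object of class `treatment_episode`: list with `patient_id`,
#'   `start`, `end` and `regimens` (a list; each regimen has `line`, `start`,
#'   `end`, `drugs`, `roles`, `failure_mode`).
#' @export
build_treatment_episode <- function(pharmacy_claims, index_date,
                                    gap_days = study_params()$episode_gap_days,
                                    params = study_params(),
                                    code_lists = default_code_lists()) {
  index_date <- as.Date(index_date)
  cl <- pharmacy_claims[pharmacy_claims$drug_class %in%
                          c("antidepressant", code_lists$augmentation_classes), ,
                        drop = FALSE]
  cl$dispense_date <- as.Date(cl$dispense_date)
  cl <- cl[cl$dispense_date >= index_date, , drop = FALSE]
  cl <- cl[order(cl$dispense_date, cl$drug_name), , drop = FALSE]
  at_index <- cl$drug_class == "antidepressant" & cl$dispense_date == index_date
  if (!any(at_index))
    stopf("no antidepressant dispensing on the index date: cohort contract violated")

  # maximal covered run: stop at the first supply gap > gap_days
  keep <- logical(nrow(cl))
  cov_end <- as.Date(NA)
  for (i in seq_len(nrow(cl))) {
    d <- cl$dispense_date[i]
    if (is.na(cov_end)) {
      keep[i] <- TRUE
      cov_end <- d + cl$days_supply[i] - 1L
    } else if (as.integer(d - cov_end) > gap_days) {
      break
    } else {
      keep[i] <- TRUE
      cov_end <- max(cov_end, d + cl$days_supply[i] - 1L)
    }
  }
  ep <- cl[keep, , drop = FALSE]
  ep_end <- max(ep$dispense_date + ep$days_supply - 1L)

  # first dispensing of each drug within the episode, in date order
  first_idx <- !duplicated(ep$drug_name)
  events <- ep[first_idx, c("drug_name", "drug_class", "dispense_date"),
               drop = FALSE]

  idx_drug <- ep$drug_name[which(ep$dispense_date == index_date &
                                   ep$drug_class == "antidepressant")[1]]
  reg <- list(line = 1L, start = index_date, drugs = idx_drug,
              roles = "core_antidepressant")
  regimens <- list()
  orphans <- character(0)

  for (j in seq_len(nrow(events))) {
    drug <- events$drug_name[j]
    if (drug %in% reg$drugs) next
    t <- events$dispense_date[j]
    is_ad <- events$drug_class[j] == "antidepressant"
    cov <- coverage_intervals(ep, reg$drugs)
    covered <- any(cov$start <= t & cov$end >= t)
    if (!covered && !is_ad) { orphans <- c(orphans, drug); next }
    cls <- classify_drug_transition(reg$start, covered, t, params)
    if (cls == "same_regimen") {
      reg$drugs <- c(reg$drugs, drug)
      reg$roles <- c(reg$roles,
                     if (is_ad) "added_antidepressant" else "augmentation")
    } else if (cls == "no_failure") {
      # non-qualifying switch: the line restarts on the new drug
      reg$start <- t
      reg$drugs <- drug
      reg$roles <- "core_antidepressant"
    } else {
      reg$end <- t - 1L
      reg$failure_mode <- if (cls == "switch_failure") "switch" else "augmentation"
      regimens[[length(regimens) + 1L]] <- reg
      if (cls == "switch_failure") {
        reg <- list(line = reg$line + 1L, start = t, drugs = drug,
                    roles = "core_antidepressant")
      } else {
        prev <- regimens[[length(regimens)]]
        reg <- list(line = prev$line + 1L, start = t,
                    drugs = c(prev$drugs, drug),
                    roles = c(prev$roles,
                              if (is_ad) "added_antidepressant" else "augmentation"))
      }
    }
  }
  reg$end <- ep_end
  reg$failure_mode <- "none"
  regimens[[length(regimens) + 1L]] <- reg

  out <- list(patient_id = if (nrow(ep)) ep$patient_id[1] else NA_character_,
              start = index_date, end = ep_end, claims = ep,
              regimens = regimens, orphan_augmentations = orphans)
  class(out) <- "treatment_episode"
  out
}

#' Assess regimen dose adequacy
#'
#' A regimen is dose-adequate when at least one of its antidepressants
#' reaches the drug's minimum adequate daily dose on a fill whose supply
#' overlaps the regimen interval; dose titration that crosses the minimum
#' mid-regimen therefore qualifies.
#'
#' @param regimen one regimen (element of `episode$regimens`).
#' @param episode_claims the episode's pharmacy claims.
#' @param dose_table named numeric vector of minimum daily doses, see
#'   [default_dose_table()].
#' @return logical.
#' @export
assess_adequate_dose <- function(regimen, episode_claims, dose_table) {
  ads <- regimen$drugs[regimen$roles %in% c("core_antidepressant",
                                            "added_antidepressant")]
  missing <- setdiff(ads, names(dose_table))
  if (length(missing))
    stopf("no minimum-dose entry for drug '%s'", missing[1])
  k <- episode_claims[episode_claims$drug_name %in% ads, , drop = FALSE]
  if (!nrow(k)) return(FALSE)
  s <- as.Date(k$dispense_date)
  e <- s + k$days_supply - 1L
  reg_end <- regimen$end %||% max(e)
  overlaps <- s <= as.Date(reg_end) & e >= as.Date(regimen$start)
  any(overlaps & !is.na(k$daily_dose) &
        k$daily_dose >= dose_table[k$drug_name])
}

#' Classify treatment resistance for one episode
#'
#' A patient is treatment-resistant when the current depression treatment
#' episode contains at least three antidepressant regimens and the first two
#' were each dose-adequate and ended in a qualifying failure (a switch in
#' the 29-180 day window, or augmentation on Day 15 or later) — the
#' operational reading of "adequate dose and duration for the first 2". The
#' audit trail records each regimen's dates, drugs, adequacy and failure
#' mode.
#'
#' @param episode a [build_treatment_episode()] result.
#' @param dose_table see [default_dose_table()].
#' @return object of class `trd_classification`: list with `trd` (logical),
#'   `n_regimens`, and `audit` (data.frame).
#' @export
classify_trd <- function(episode, dose_table = default_dose_table()) {
  regs <- episode$regimens
  adequacy <- vapply(regs, assess_adequate_dose, logical(1),
                     episode_claims = episode$claims, dose_table = dose_table)
  failed <- vapply(regs, function(r) r$failure_mode != "none", logical(1))
  n <- length(regs)
  trd <- n >= 3L && adequacy[1] && failed[1] && adequacy[2] && failed[2]
  audit <- data.frame(
    line = vapply(regs, function(r) r$line, integer(1)),
    start = as.Date(vapply(regs, function(r) as.character(r$start), character(1))),
    end = as.Date(vapply(regs, function(r) as.character(r$end), character(1))),
    drugs = vapply(regs, function(r)
      paste(sprintf("%s(%s)", r$drugs, r$roles), collapse = ";"), character(1)),
    dose_adequate = adequacy,
    failure_mode = vapply(regs, function(r) r$failure_mode, character(1)),
    stringsAsFactors = FALSE)
  out <- list(trd = trd, n_regimens = n, audit = audit)
  class(out) <- "trd_classification"
  out
}

#' @export
print.trd_classification <- function(x, ...) {
  cat(sprintf("Treatment-resistant: %s (%d regimen%s)\n",
              x$trd, x$n_regimens, if (x$n_regimens == 1) "" else "s"))
  print(x$audit)
  invisible(x)
}

#' Classify treatment resistance for a whole cohort
#'
#' Builds each eligible patient's treatment episode from pharmacy claims and
#' applies [classify_trd()].
#'
#' @param cohort the `cohort` data.frame from [build_cohort()].
#' @param pharmacy_claims pharmacy claims table (all patients).
#' @param dose_table see [default_dose_table()].
#' @param params a [study_params()].
#' @param code_lists a [default_code_lists()].
#' @return the cohort data.frame with a logical `trd` column; per-patient
#'   audit trails in `attr(, "audits")`.
#' @export
classify_cohort <- function(cohort, pharmacy_claims,
                            dose_table = default_dose_table(),
                            params = study_params(),
                            code_lists = default_code_lists()) {
  sp <- split(pharmacy_claims,
              factor(pharmacy_claims$patient_id, levels = cohort$patient_id))
  audits <- vector("list", nrow(cohort))
  trd <- logical(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    ep <- build_treatment_episode(sp[[i]], cohort$index_date[i],
                                  params$episode_gap_days, params, code_lists)
    cls <- classify_trd(ep, dose_table)
    trd[i] <- cls$trd
    audits[[i]] <- cls$audit
  }
  names(audits) <- cohort$patient_id
  cohort$trd <- trd
  attr(cohort, "audits") <- audits
  cohort
}
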