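# Fixture builders and independent brute-force oracles used across tests.

ORIGIN <- as.Date("2013-02-01")

ph_fix <- function(day, drug = "sertraline", class = "antidepressant",
                   dose = 50, supply = 30L, id = "p1", origin = ORIGIN) {
  data.frame(patient_id = id, dispense_date = origin + day, drug_name = drug,
             drug_class = class, daily_dose = dose,
             days_supply = as.integer(supply), payer_cost = 10,
             patient_cost = 2, stringsAsFactors = FALSE)
}

med_fix <- function(day, icd = "3004", setting = "outpatient", proc = "",
                    los = 1L, payer = 100, patient = 20, id = "p1",
                    origin = ORIGIN) {
  data.frame(patient_id = id, service_start = origin + day,
             service_end = origin + day + los - 1L, setting = setting,
             icd_codes = icd, procedure_codes = proc, payer_cost = payer,
             patient_cost = patient, stringsAsFactors = FALSE)
}

enroll_fix <- function(from = -400L, to = 770L, id = "p1", origin = ORIGIN) {
  data.frame(patient_id = id, start = origin + from, end = origin + to,
             has_pharmacy = TRUE, has_medical = TRUE, stringsAsFactors = FALSE)
}

patient_fix <- function(age = 40, id = "p1", origin = ORIGIN,
                        death_date = as.Date(NA)) {
  data.frame(patient_id = id, birth_date = origin - ceiling(365.25 * age) - 10L,
             sex = "female", death_date = death_date, stringsAsFactors = FALSE)
}

# A textbook-eligible single-patient fixture; pieces can be overridden.
eligible_fixture <- function(dx_day = 10L, origin = ORIGIN) {
  list(patient = patient_fix(origin = origin),
       pharmacy = rbind(ph_fix(0L, origin = origin),
                        ph_fix(25L, origin = origin)),
       medical = med_fix(dx_day, origin = origin),
       enrollment = enroll_fix(origin = origin),
       index = origin)
}

# ---------------------------------------------------------------------------
# Brute-force evaluator of the regimen-failure rules, written directly from
# the textual rules on a day grid, independent of the interval arithmetic in
# the package. Takes a one-patient pharmacy claims table; returns the number
# of therapy lines and the resistance label.
brute_force_trd <- function(pharmacy, index_date, dose_table = default_dose_table(),
                            episode_gap = 180L) {
  ph <- pharmacy[order(as.Date(pharmacy$dispense_date),
                       pharmacy$drug_name), , drop = FALSE]
  ph$off <- as.integer(as.Date(ph$dispense_date) - as.Date(index_date))
  ph <- ph[ph$off >= 0L, , drop = FALSE]
  horizon <- max(ph$off + ph$days_supply) + 5L
  day_covered <- function(rows, d) {
    any(rows$off + 1L <= d & d <= rows$off + rows$days_supply)
  }
  # episode membership on the day grid: running covered-day frontier
  keep <- logical(nrow(ph)); frontier <- -1L
  for (i in seq_len(nrow(ph))) {
    if (frontier < 0L || ph$off[i] - frontier <= episode_gap) {
      keep[i] <- TRUE
      frontier <- max(frontier, ph$off[i] + ph$days_supply[i] - 1L)
    } else break
  }
  ph <- ph[keep, , drop = FALSE]

  firsts <- ph[!duplicated(ph$drug_name), , drop = FALSE]
  line_start <- 1L                      # Day 1 = index day
  line_drugs <- firsts$drug_name[firsts$off == 0L &
                                   firsts$drug_class == "antidepressant"][1]
  lines <- list()
  for (i in seq_len(nrow(firsts))) {
    drug <- firsts$drug_name[i]
    if (drug %in% line_drugs) next
    day <- firsts$off[i] + 1L           # calendar Day number of the new drug
    rows <- ph[ph$drug_name %in% line_drugs, , drop = FALSE]
    on_supply <- day_covered(rows, day)
    day_in_line <- day - line_start + 1L
    is_ad <- firsts$drug_class[i] == "antidepressant"
    if (on_supply) {
      if (day_in_line >= 15L) {         # augmentation on Day 15 or later
        lines[[length(lines) + 1L]] <- list(drugs = line_drugs,
                                            start = line_start,
                                            end = day - 1L)
        line_drugs <- c(line_drugs, drug)
        line_start <- day
      } else {
        line_drugs <- c(line_drugs, drug)
      }
    } else if (is_ad) {
      gap <- day - line_start
      if (gap >= 29L && gap <= 180L) {  # qualifying switch
        lines[[length(lines) + 1L]] <- list(drugs = line_drugs,
                                            start = line_start,
                                            end = day - 1L)
        line_drugs <- drug
        line_start <- day
      } else {                          # too early / too late: fresh trial
        line_drugs <- drug
        line_start <- day
      }
    }
  }
  lines[[length(lines) + 1L]] <- list(drugs = line_drugs, start = line_start,
                                      end = horizon)
  ad_ok <- function(ln) {
    rows <- ph[ph$drug_name %in% ln$drugs &
                 ph$drug_class == "antidepressant", , drop = FALSE]
    if (!nrow(rows)) return(FALSE)
    any(rows$off + 1L <= ln$end & rows$off + rows$days_supply >= ln$start &
          rows$daily_dose >= dose_table[rows$drug_name])
  }
  n <- length(lines)
  trd <- n >= 3L && ad_ok(lines[[1]]) && ad_ok(lines[[2]])
  list(n_lines = n, trd = trd)
}

# ---------------------------------------------------------------------------
# Plain nested-loop reimplementation of the greedy matching policy.
brute_force_greedy <- function(scores, trd, ratio, caliper, ids) {
  trd <- as.logical(trd)
  cases <- ids[trd][order(-scores[trd], ids[trd])]
  pool <- data.frame(id = ids[!trd], s = scores[!trd],
                     stringsAsFactors = FALSE)
  pool$used <- FALSE
  out <- NULL; unmatched <- character(0)
  for (cid in cases) {
    cs <- scores[ids == cid]
    taken <- 0L
    while (taken < ratio) {
      free <- which(!pool$used)
      if (!length(free)) break
      d <- abs(pool$s[free] - cs)
      ok <- free[d <= caliper + 1e-9]
      if (!length(ok)) break
      dd <- abs(pool$s[ok] - cs)
      best <- ok[order(dd, pool$id[ok])][1]
      pool$used[best] <- TRUE
      out <- rbind(out, data.frame(case_id = cid, control_id = pool$id[best],
                                   distance = abs(pool$s[best] - cs),
                                   stringsAsFactors = FALSE))
      taken <- taken + 1L
    }
    if (taken == 0L) unmatched <- c(unmatched, cid)
  }
  list(matches = out, unmatched = unmatched)
}
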