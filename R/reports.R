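# Report rendering: balance, utilization and cost tables as CSV plus a
# plain-text summary. Output is fully deterministic (no timestamps) so that
# seeded pipeline runs are byte-reproducible.

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, format = "fg", digits = digits))
}

model_result_row <- function(r, outcome, year) {
  data.frame(outcome = outcome, year = year, family = r$family,
             n_trd = unname(r$n["trd"]), n_control = unname(r$n["control"]),
             mean_trd = r$mean_trd, mean_control = r$mean_control,
             estimate = r$difference, ratio = r$ratio,
             ci_lower = r$ci_lower, ci_upper = r$ci_upper,
             stringsAsFactors = FALSE)
}

or_result_rows <- function(r, outcome) {
  data.frame(outcome = outcome, year = r$or_table$year, family = "gee_logistic",
             n_trd = NA_integer_, n_control = NA_integer_,
             mean_trd = NA_real_, mean_control = NA_real_,
             estimate = r$or_table$or, ratio = r$or_table$or,
             ci_lower = r$or_table$lower, ci_upper = r$or_table$upper,
             stringsAsFactors = FALSE)
}

#' Render analysis reports
#'
#' Writes a balance table (pre/post matching standardized differences and
#' test p-values), a utilization table (odds ratios and adjusted mean
#' differences per follow-up year) and a cost table, as CSV files plus a
#' human-readable text summary. Empty inputs yield headers-only files.
#'
#' @param dir output directory (created if needed).
#' @param balance data.frame from [balance_table()], or NULL.
#' @param utilization data.frame of utilization result rows (see
#'   `model_result_row` layout), or NULL.
#' @param costs data.frame of cost result rows, or NULL.
#' @return character vector of file paths, invisibly.
#' @export
render_reports <- function(dir, balance = NULL, utilization = NULL,
                           costs = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  empty_rows <- function() data.frame(
    outcome = character(0), year = integer(0), family = character(0),
    n_trd = integer(0), n_control = integer(0), mean_trd = numeric(0),
    mean_control = numeric(0), estimate = numeric(0), ratio = numeric(0),
    ci_lower = numeric(0), ci_upper = numeric(0))
  if (is.null(balance))
    balance <- data.frame(covariate = character(0), smd_unmatched = numeric(0),
                          p_unmatched = numeric(0), smd_matched = numeric(0),
                          p_matched = numeric(0))
  if (is.null(utilization)) utilization <- empty_rows()
  if (is.null(costs)) costs <- empty_rows()

  paths <- file.path(dir, c("balance.csv", "utilization.csv", "costs.csv",
                            "summary.txt"))
  utils::write.csv(balance, paths[1], row.names = FALSE, na = "NA")
  utils::write.csv(utilization, paths[2], row.names = FALSE, na = "NA")
  utils::write.csv(costs, paths[3], row.names = FALSE, na = "NA")

  con <- file(paths[4], "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Treatment-resistant vs non-resistant depression: adjusted outcomes")
  w("")
  w("== Covariate balance (standardized mean differences) ==")
  if (nrow(balance)) {
    for (i in seq_len(nrow(balance))) {
      w("  %-28s unmatched % .4f   matched %s", balance$covariate[i],
        balance$smd_unmatched[i],
        if ("smd_matched" %in% names(balance))
          sprintf("% .4f", balance$smd_matched[i]) else "NA")
    }
  } else w("  (no rows)")
  w("")
  w("== Healthcare utilization ==")
  if (nrow(utilization)) {
    for (i in seq_len(nrow(utilization))) {
      w("  %-22s year %d  estimate %s (95%% CI %s to %s) [%s]",
        utilization$outcome[i], utilization$year[i],
        fmt_num(utilization$estimate[i]), fmt_num(utilization$ci_lower[i]),
        fmt_num(utilization$ci_upper[i]), utilization$family[i])
    }
  } else w("  (no rows)")
  w("")
  w("== Healthcare costs (US$) ==")
  if (nrow(costs)) {
    for (i in seq_len(nrow(costs))) {
      w("  %-22s year %d  difference %s (95%% CI %s to %s) [%s]",
        costs$outcome[i], costs$year[i], fmt_num(costs$estimate[i]),
        fmt_num(costs$ci_lower[i]), fmt_num(costs$ci_upper[i]),
        costs$family[i])
    }
  } else w("  (no rows)")
  invisible(paths)
}
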