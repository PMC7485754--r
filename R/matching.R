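#' Elixhauser comorbidity score
#'
#' Counts the distinct Elixhauser comorbidity categories with at least one
#' matching diagnosis code among the supplied claims (callers pass the
#' baseline-window claims). The score is an integer between 0 and the number
#' of configured categories (30 in the shipped map).
#'
#' @param medical_claims claims restricted to the window of interest.
#' @param category_map named list of ICD prefixes per category, see
#'   [default_elixhauser_map()].
#' @return integer score.
#' @export
compute_elixhauser <- function(medical_claims,
                               category_map = default_elixhauser_map()) {
  if (is.null(medical_claims) || nrow(medical_claims) == 0L) return(0L)
  codes <- unique(unlist(split_codes(medical_claims$icd_codes)))
  sum(vapply(category_map,
             function(pref) any(code_matches(codes, pref)), logical(1)))
}

#' Fit the propensity model
#'
#' Logistic regression of treatment-resistance status on age at index, sex,
#' diagnosis-category indicators, the four baseline comorbidity flags and
#' the Elixhauser score. Covariates with no variation in the data are
#' dropped from the model formula automatically (they carry no information
#' and would break the fit on small fixtures).
#'
#' @param data data.frame with a logical/0-1 `trd` column and the covariate
#'   columns named as in [extract_baseline_covariates()].
#' @param formula optional model formula overriding the default covariate
#'   set.
#' @return object of class `propensity_model`: list with `model`, `scores`
#'   (fitted probabilities in (0,1), named by `patient_id` when present) and
#'   `formula`.
#' @export
fit_propensity <- function(data, formula = NULL) {
  if (length(unique(data$trd)) < 2L)
    stopf("both classes must be present to fit a propensity model")
  if (is.null(formula)) {
    cand <- c("age_at_index", "sex", "diagnosis_category", "anxiety",
              "personality_disorder", "substance_abuse", "ptsd", "elixhauser")
    cand <- cand[cand %in% names(data)]
    cand <- cand[vapply(cand, function(v) length(unique(data[[v]])) > 1L,
                        logical(1))]
    if (!length(cand)) stopf("no covariates with variation available")
    formula <- stats::reformulate(cand, response = "trd")
  }
  d <- data
  d$trd <- as.integer(d$trd)
  fit <- stats::glm(formula, data = d, family = stats::binomial())
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p < eps) || any(p > 1 - eps)) {
    co <- stats::coef(fit)
    worst <- names(co)[which.max(abs(co))]
    stopf("complete or quasi-complete separation detected (largest coefficient: %s)",
          worst)
  }
  if (!is.null(data$patient_id)) names(p) <- data$patient_id
  out <- list(model = fit, scores = unname(p), patient_id = data$patient_id,
              formula = formula)
  class(out) <- "propensity_model"
  out
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity model:", deparse(x$formula), "\n")
  cat(sprintf("  %d patients, score range [%.4f, %.4f]\n",
              length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Greedy 1:N caliper matching
#'
#' Sequential greedy nearest-neighbour matching without replacement. Cases
#' are processed in a fixed, documented order (descending propensity score,
#' ties broken by patient id); each case takes up to `ratio` nearest
#' still-unmatched controls whose score lies within the caliper (inclusive,
#' on the probability scale, with a 1e-9 numerical tolerance). Cases with no
#' in-caliper control are reported unmatched; fewer than `ratio` controls is
#' allowed (variable-ratio matching).
#'
#' @param scores numeric propensity scores.
#' @param trd logical/0-1 case indicator.
#' @param ratio maximum controls per case (default 4).
#' @param caliper maximum |score difference| allowed (default 0.02).
#' @param ids optional patient ids (defaults to positions).
#' @param order `"score"` for the deterministic default, `"random"` for a
#'   seeded random case order.
#' @param seed used only when `order = "random"`.
#' @return object of class `matched_cohort`: list with `matches`
#'   (case_id, control_id, distance), `unmatched_case_ids`, `ratio`,
#'   `caliper`.
#' @export
greedy_match <- function(scores, trd, ratio = 4L, caliper = 0.02,
                         ids = NULL, order = c("score", "random"),
                         seed = NULL) {
  order <- match.arg(order)
  stopifnot(length(scores) == length(trd), ratio >= 1L, caliper > 0)
  trd <- as.logical(trd)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  tol <- 1e-9
  case_i <- which(trd)
  ctrl_i <- which(!trd)
  case_ord <- if (order == "random") {
    if (is.null(seed)) stopf("seed required for random case order")
    with_seed(seed, sample(case_i))
  } else {
    case_i[order(-scores[case_i], ids[case_i])]
  }
  avail <- rep(TRUE, length(ctrl_i))
  cs <- scores[ctrl_i]; cid <- ids[ctrl_i]
  m_case <- character(0); m_ctrl <- character(0); m_dist <- numeric(0)
  unmatched <- character(0)
  for (ci in case_ord) {
    d <- abs(cs - scores[ci])
    cand <- which(avail & d <= caliper + tol)
    if (!length(cand)) { unmatched <- c(unmatched, ids[ci]); next }
    cand <- cand[order(d[cand], cid[cand])]
    take <- utils::head(cand, ratio)
    avail[take] <- FALSE
    m_case <- c(m_case, rep(ids[ci], length(take)))
    m_ctrl <- c(m_ctrl, cid[take])
    m_dist <- c(m_dist, d[take])
  }
  out <- list(matches = data.frame(case_id = m_case, control_id = m_ctrl,
                                   distance = m_dist, stringsAsFactors = FALSE),
              unmatched_case_ids = unmatched,
              ratio = as.integer(ratio), caliper = caliper)
  class(out) <- "matched_cohort"
  out
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("Matched cohort: %d cases, %d controls (ratio <= %d, caliper %.3g)\n",
              length(unique(x$matches$case_id)), nrow(x$matches), x$ratio,
              x$caliper))
  if (length(x$unmatched_case_ids))
    cat(sprintf("  unmatched cases: %d\n", length(x$unmatched_case_ids)))
  invisible(x)
}

#' Re-verify matched-cohort invariants
#'
#' Independent post-hoc checker for a [greedy_match()] result: every control
#' used at most once, no case with more than `ratio` controls, and every
#' matched pair within the caliper.
#'
#' @param m a `matched_cohort`.
#' @param scores,ids the score vector and ids used for matching.
#' @return TRUE, or a character vector of violated invariants.
#' @export
check_matched_cohort <- function(m, scores, ids) {
  s <- scores[match(c(m$matches$case_id, m$matches$control_id), ids)]
  k <- nrow(m$matches)
  bad <- character(0)
  if (anyDuplicated(m$matches$control_id)) bad <- c(bad, "control reused")
  if (k && max(table(m$matches$case_id)) > m$ratio) bad <- c(bad, "ratio cap exceeded")
  if (k) {
    d <- abs(s[seq_len(k)] - s[k + seq_len(k)])
    if (any(d > m$caliper + 1e-9)) bad <- c(bad, "caliper violated")
  }
  if (length(bad)) bad else TRUE
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (difference in means over the pooled
#' standard deviation) and two-sample test p-values (t-test for continuous
#' covariates, chi-square for binary/categorical) comparing resistant and
#' non-resistant arms, in the full cohort and in the matched sample.
#'
#' @param data cohort data.frame with `trd` and covariate columns.
#' @param matched a `matched_cohort`, or NULL for pre-matching only.
#' @param covariates covariate names; categorical covariates are expanded to
#'   indicator columns.
#' @return data.frame with one row per (expanded) covariate.
#' @export
balance_table <- function(data, matched = NULL,
                          covariates = c("age_at_index", "sex", "anxiety",
                                         "personality_disorder",
                                         "substance_abuse", "ptsd",
                                         "elixhauser", "diagnosis_category")) {
  expand <- function(d) {
    out <- list()
    for (v in covariates) {
      x <- d[[v]]
      if (is.numeric(x)) {
        out[[v]] <- as.numeric(x)
      } else if (is.logical(x)) {
        out[[v]] <- as.numeric(x)
      } else {
        x <- as.character(x)
        for (lv in sort(unique(as.character(data[[v]])))) {
          out[[paste0(v, ":", lv)]] <- as.numeric(x == lv)
        }
      }
    }
    as.data.frame(out, check.names = FALSE)
  }
  smd <- function(x, g) {
    m1 <- mean(x[g]); m0 <- mean(x[!g])
    s <- sqrt((stats::var(x[g]) + stats::var(x[!g])) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (m1 - m0) / s
  }
  pval <- function(x, g) {
    if (length(unique(x)) <= 2L) {
      tb <- table(factor(x), factor(g))
      if (any(dim(tb) < 2L)) return(NA_real_)
      suppressWarnings(stats::chisq.test(tb)$p.value)
    } else {
      stats::t.test(x[g], x[!g])$p.value
    }
  }
  g_all <- as.logical(data$trd)
  X <- expand(data)
  res <- data.frame(covariate = names(X),
                    smd_unmatched = vapply(X, smd, numeric(1), g = g_all),
                    p_unmatched = vapply(X, pval, numeric(1), g = g_all),
                    stringsAsFactors = FALSE)
  if (!is.null(matched)) {
    keep_ids <- c(unique(matched$matches$case_id), matched$matches$control_id)
    sub <- data[data$patient_id %in% keep_ids, , drop = FALSE]
    gm <- as.logical(sub$trd)
    Xm <- expand(sub)
    res$smd_matched <- vapply(Xm, smd, numeric(1), g = gm)
    res$p_matched <- vapply(Xm, pval, numeric(1), g = gm)
  }
  rownames(res) <- NULL
  res
}
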