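# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Normalize ICD codes
#'
#' Uppercases and strips dots/whitespace so that prefix matching implements
#' "296.2x"-style semantics.
#'
#' @param x character vector of ICD-9/ICD-10 codes.
#' @return normalized character vector.
#' @export
normalize_icd <- function(x) gsub("[. ]", "", toupper(trimws(as.character(x))))

# Split a ";"-delimited code field into a normalized character vector.
split_codes <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), normalize_icd)
}

# TRUE for each code that starts with any prefix and with none of `exclude`.
code_matches <- function(codes, prefixes, exclude = character()) {
  if (length(codes) == 0L) return(logical(0))
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  for (e in exclude) hit <- hit & !startsWith(codes, e)
  hit
}

# Any code on any claim row matches the prefix list?
claims_match_codes <- function(icd_field, prefixes, exclude = character()) {
  vapply(split_codes(icd_field), function(cc) any(code_matches(cc, prefixes, exclude)),
         logical(1))
}

days_between <- function(from, to) as.integer(as.Date(to) - as.Date(from))

age_at <- function(birth_date, date) {
  floor(as.numeric(as.Date(date) - as.Date(birth_date)) / 365.25)
}

# Merge sorted, possibly touching enrollment intervals; gap of 0 days merges.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  }
  o <- order(start, end)
  start <- as.Date(start)[o]; end <- as.Date(end)[o]
  ms <- start[1]; me <- end[1]
  out_s <- as.Date(character()); out_e <- as.Date(character())
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (as.numeric(start[i] - me) <= 1) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
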