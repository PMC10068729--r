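#' Five-word test raw and weighted totals
#'
#' The five-word recall test presents five words and probes recall twice
#' (immediately and after a delay), each time first by free recall and then
#' with semantic cues for the words not retrieved freely. The raw total is
#' the number of words recalled over the four probes (0..10); the weighted
#' total doubles the free recalls: `weighted = cued total + 2 * free total`
#' (0..20). Algebraically, `weighted = raw + free total`.
#'
#' @param free_immediate,cued_immediate,free_delayed,cued_delayed Integer
#'   counts in 0..5; within each phase free + cued cannot exceed 5.
#' @return A tibble with columns `raw_total` (0..10) and `weighted_total`
#'   (0..20), one row per input element.
#' @export
#' @examples
#' fwt_scores(5, 0, 5, 0) # perfect free recall: raw 10, weighted 20
#' fwt_scores(3, 2, 2, 2) # raw 9, weighted 14
fwt_scores <- function(free_immediate, cued_immediate, free_delayed,
                       cued_delayed) {
  counts <- list(free_immediate = free_immediate,
                 cued_immediate = cued_immediate,
                 free_delayed = free_delayed, cued_delayed = cued_delayed)
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (!is.numeric(x) || any(is.na(x)) || any(x != round(x)) ||
        any(x < 0) || any(x > 5)) {
      abort(sprintf("`%s` must be integer counts in 0..5.", nm),
            class = "cogsieve_validation_error")
    }
  }
  if (any(free_immediate + cued_immediate > 5) ||
      any(free_delayed + cued_delayed > 5)) {
    abort("free + cued recalls cannot exceed 5 words within a phase.",
          class = "cogsieve_validation_error")
  }
  free <- free_immediate + free_delayed
  cued <- cued_immediate + cued_delayed
  tibble::tibble(raw_total = as.integer(free + cued),
                 weighted_total = as.integer(cued + 2L * free))
}

#' Trail making test shifting cost (part B minus part A)
#'
#' @param time_a_s,time_b_s Completion times in seconds (positive).
#' @return `time_b_s - time_a_s`, in seconds. A negative result (part B
#'   faster than part A) is arithmetically valid but unusual, and raises a
#'   warning.
#' @export
#' @examples
#' tmt_delta(26.62, 52.37)
tmt_delta <- function(time_a_s, time_b_s) {
  if (!is.numeric(time_a_s) || !is.numeric(time_b_s) ||
      any(is.na(time_a_s)) || any(is.na(time_b_s)) ||
      any(time_a_s <= 0) || any(time_b_s <= 0)) {
    abort("TMT times must be positive numbers of seconds.",
          class = "cogsieve_validation_error")
  }
  delta <- time_b_s - time_a_s
  if (any(delta < 0)) {
    warn("TMT part B faster than part A for some records (negative B - A).")
  }
  delta
}

#' Number coding test summary counts
#'
#' @param good,wrong Nonnegative integer counts of correct and incorrect
#'   symbol substitutions over the 2-minute test.
#' @return A tibble with columns `good`, `wrong`, `total` (= good + wrong).
#' @export
#' @examples
#' nct_summary(33, 2)
nct_summary <- function(good, wrong) {
  for (nm in c("good", "wrong")) {
    x <- get(nm)
    if (!is.numeric(x) || any(is.na(x)) || any(x != round(x)) || any(x < 0)) {
      abort(sprintf("`%s` must be nonnegative integer counts.", nm),
            class = "cogsieve_validation_error")
    }
  }
  tibble::tibble(good = as.integer(good), wrong = as.integer(wrong),
                 total = as.integer(good + wrong))
}

#' System usability scale score
#'
#' Standard SUS arithmetic for ten 5-point Likert items: odd items contribute
#' `answer - 1`, even items `5 - answer`, and the sum is rescaled by 2.5,
#' giving a score in \[0, 100\] in steps of 2.5.
#'
#' @param responses An integer vector of length 10 (one answer per item, in
#'   1..5), or a 10-column matrix/data frame with one respondent per row.
#' @return A numeric score (or vector of scores) in \[0, 100\].
#' @export
#' @examples
#' sus_score(rep(3, 10)) # midpoint: 50
#' sus_score(rep(c(5, 1), 5)) # maximal agreement pattern: 100
sus_score <- function(responses) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (is.matrix(responses)) {
    if (ncol(responses) != 10) {
      abort("SUS responses must have exactly 10 items.",
            class = "cogsieve_validation_error")
    }
    return(apply(responses, 1, sus_score))
  }
  if (length(responses) != 10 || !is.numeric(responses) ||
      any(is.na(responses)) || any(responses != round(responses)) ||
      any(responses < 1) || any(responses > 5)) {
    abort("SUS responses must be 10 integers in 1..5.",
          class = "cogsieve_validation_error")
  }
  odd <- responses[c(1, 3, 5, 7, 9)]
  even <- responses[c(2, 4, 6, 8, 10)]
  2.5 * (sum(odd - 1) + sum(5 - even))
}

#' System usability scale category
#'
#' Published cutoffs: excellent if >= 86, good if >= 73, acceptable if >= 52;
#' scores below 52 are labelled `not_acceptable` (the scale's literature names
#' no category below acceptable).
#'
#' @param score SUS score(s) in \[0, 100\].
#' @return A factor with ordered levels
#'   `not_acceptable < acceptable < good < excellent`.
#' @export
#' @examples
#' sus_category(c(92, 79.5, 60, 40))
sus_category <- function(score) {
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0) ||
      any(score > 100)) {
    abort("SUS scores must lie in [0, 100].",
          class = "cogsieve_validation_error")
  }
  cut(score, breaks = c(-Inf, 52, 73, 86, Inf),
      labels = c("not_acceptable", "acceptable", "good", "excellent"),
      right = FALSE, ordered_result = TRUE)
}

#' Read a norm table for score standardization
#'
#' Norm tables map a raw reference-battery score, an age band and an
#' education-level set to a normative mean/SD and an output scale. The CSV
#' columns are `score, age_lo, age_hi, education_levels, mean, sd, scale`
#' with `education_levels` a pipe-joined set (e.g. `1|2`), the age band
#' half-open `[age_lo, age_hi)`, and `scale` one of `z` or `wais_scaled`.
#' Published norm tables are not redistributed here; a synthetic example
#' table ships under `inst/extdata/synthetic_norms.csv`.
#'
#' @param path Path to a norm-table CSV.
#' @return A tibble of norm entries.
#' @export
read_norm_table <- function(path) {
  norms <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("score", "age_lo", "age_hi", "education_levels", "mean", "sd",
              "scale")
  missing <- setdiff(needed, names(norms))
  if (length(missing)) {
    abort(paste0("Norm table lacks columns: ",
                 paste(missing, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  if (any(norms$sd <= 0)) {
    abort("Norm table SDs must be positive.",
          class = "cogsieve_validation_error")
  }
  norms
}

#' Standardize raw scores against a norm table
#'
#' Looks up the norm band matching each participant's age (half-open band)
#' and education level, and returns `z = (raw - mean) / sd`, or the WAIS-style
#' scaled score `10 + 3 z` where the matching entry's scale is `wais_scaled`.
#' A participant with no matching band is an error, never a silent
#' imputation.
#'
#' @param raw Raw score values.
#' @param score Score name (single string, matched against `norms$score`).
#' @param age,education_level Vectors aligned with `raw`.
#' @param norms A norm table from [read_norm_table()].
#' @return A numeric vector of standardized values.
#' @export
standardize <- function(raw, score, age, education_level, norms) {
  n <- length(raw)
  entries <- norms[norms$score == score, ]
  if (nrow(entries) == 0) {
    abort(sprintf("missing norm: no entries for score `%s`.", score),
          class = "cogsieve_norm_error")
  }
  vapply(seq_len(n), function(i) {
    lev <- strsplit(entries$education_levels, "|", fixed = TRUE)
    hit <- which(age[i] >= entries$age_lo & age[i] < entries$age_hi &
                   vapply(lev, function(l) {
                     as.character(education_level[i]) %in% l
                   }, logical(1)))
    if (length(hit) == 0) {
      abort(sprintf(
        "missing norm: score `%s`, age %s, education level %s.",
        score, age[i], education_level[i]), class = "cogsieve_norm_error")
    }
    e <- entries[hit[1], ]
    z <- (raw[i] - e$mean) / e$sd
    if (identical(e$scale, "wais_scaled")) 10 + 3 * z else z
  }, numeric(1))
}
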