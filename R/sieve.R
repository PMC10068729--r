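#' Construct a two-step sieve decision rule
#'
#' The clinician-guided screening rule proceeds in two stages: step 1 flags
#' an amnestic syndrome of the hippocampal type (five-word-test total at or
#' below the primary threshold, clinically established at 9); step 2 then
#' looks for a dysexecutive/speed deficit among the remaining participants
#' (5-WT total of 10), flagging those whose secondary score falls strictly
#' beyond the secondary threshold in the pathological direction.
#'
#' @param secondary_score One of `nct_good`, `nct_total`, `nct_wrong`,
#'   `tmt_a_s`, `tmt_b_s`, `tmt_delta_s` (cohort column names).
#' @param secondary_threshold Real threshold for the secondary score
#'   (`-Inf` makes step 2 flag nobody, `Inf`/`-Inf` in the pathological
#'   direction flags every remaining participant).
#' @param direction `"less_than"` (fewer answers = worse; default for
#'   `nct_good`/`nct_total`) or `"greater_than"` (more errors or seconds =
#'   worse; default otherwise).
#' @param primary_threshold Integer 0..10; step 1 flags `fwt_total <=`
#'   this value.
#' @return A list of class `sieve_rule`.
#' @export
#' @examples
#' rule <- sieve_rule("nct_good", 15)
#' classify_sieve(tibble::tibble(fwt_total = c(8, 10, 10),
#'                               nct_good = c(30, 14, 20)), rule)
sieve_rule <- function(secondary_score, secondary_threshold,
                       direction = default_direction(secondary_score),
                       primary_threshold = 9L) {
  allowed <- c("nct_good", "nct_total", "nct_wrong", "tmt_a_s", "tmt_b_s",
               "tmt_delta_s")
  if (!secondary_score %in% allowed) {
    abort(paste0("`secondary_score` must be one of: ",
                 paste(allowed, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  direction <- match.arg(direction, c("less_than", "greater_than"))
  if (!is.numeric(primary_threshold) || primary_threshold < 0 ||
      primary_threshold > 10) {
    abort("`primary_threshold` must lie in 0..10.",
          class = "cogsieve_validation_error")
  }
  structure(list(primary_threshold = primary_threshold,
                 secondary_score = secondary_score,
                 direction = direction,
                 secondary_threshold = secondary_threshold),
            class = "sieve_rule")
}

#' Default pathological direction for a secondary score
#'
#' Fewer good/total answers is worse (`less_than`); more wrong answers or
#' more seconds is worse (`greater_than`).
#'
#' @param secondary_score Secondary score name.
#' @return `"less_than"` or `"greater_than"`.
#' @export
default_direction <- function(secondary_score) {
  if (secondary_score %in% c("nct_good", "nct_total")) "less_than"
  else "greater_than"
}

#' Apply a sieve rule to participant records
#'
#' @param data A data frame with columns `fwt_total` and the rule's secondary
#'   score (no missing values: a record lacking a required score is an error,
#'   never imputed).
#' @param rule A [sieve_rule()].
#' @return A logical vector: `TRUE` = screen positive.
#' @export
classify_sieve <- function(data, rule) {
  stopifnot(inherits(rule, "sieve_rule"))
  needed <- c("fwt_total", rule$secondary_score)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  fwt <- data$fwt_total
  sec <- data[[rule$secondary_score]]
  if (any(is.na(fwt)) || any(is.na(sec))) {
    abort("Missing scores in records; sieve classification does not impute.",
          class = "cogsieve_validation_error")
  }
  step1 <- fwt <= rule$primary_threshold
  step2 <- if (rule$direction == "less_than") {
    sec < rule$secondary_threshold
  } else {
    sec > rule$secondary_threshold
  }
  step1 | (!step1 & step2)
}

#' Confusion counts and operating characteristics
#'
#' @param predictions,labels Aligned logical (or 0/1) vectors; `TRUE`/1 =
#'   positive (case).
#' @return A one-row tibble with counts `tp, fp, tn, fn` and `sensitivity`,
#'   `specificity`, `ppv`, `npv`. PPV/NPV are `NA` (the undefined flag) when
#'   their denominator is zero.
#' @export
#' @examples
#' confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length.",
          class = "cogsieve_validation_error")
  }
  p <- as.logical(predictions)
  y <- as.logical(labels)
  if (any(is.na(p)) || any(is.na(y))) {
    abort("`predictions` and `labels` must not contain missing values.",
          class = "cogsieve_validation_error")
  }
  tp <- sum(p & y); fp <- sum(p & !y); tn <- sum(!p & !y); fn <- sum(!p & y)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn)
  )
}

#' Optimize the sieve's secondary threshold under a sensitivity floor
#'
#' Chooses the secondary threshold of the full two-step rule to maximize
#' training specificity subject to full-rule training sensitivity of at least
#' `sens_min`. The candidate grid is the set of distinct secondary-score
#' values observed among training participants above the primary threshold
#' (the step-2 subgroup), plus `-Inf`/`Inf` sentinels ("flag nobody" /
#' "flag everybody remaining"); any other real threshold is equivalent to one
#' of these on the training set. Ties in specificity are broken towards the
#' rule flagging fewest positives (most conservative), then towards the
#' smaller threshold. If no candidate satisfies the floor, the candidate
#' maximizing sensitivity is returned, ties broken by higher specificity.
#'
#' @param data Training records (data frame with `fwt_total` and the
#'   secondary score).
#' @param labels Logical/0-1 case labels aligned with `data` (must contain
#'   both classes).
#' @param secondary_score,direction,primary_threshold See [sieve_rule()].
#' @param sens_min Sensitivity floor (default 0.95).
#' @return A list with `rule` (the frozen [sieve_rule()]), `threshold`,
#'   `feasible` (whether the floor was attainable on training), and `metrics`
#'   (the achieved training [confusion_metrics()] row).
#' @export
optimize_secondary_threshold <- function(data, labels, secondary_score,
                                         direction =
                                           default_direction(secondary_score),
                                         sens_min = 0.95,
                                         primary_threshold = 9L) {
  y <- as.logical(labels)
  if (length(unique(y)) < 2) {
    abort("Training labels must contain both classes.",
          class = "cogsieve_validation_error")
  }
  subgroup <- data$fwt_total > primary_threshold
  candidates <- sort(unique(c(-Inf, data[[secondary_score]][subgroup], Inf)))
  grid <- purrr::map_dfr(candidates, function(th) {
    rule <- sieve_rule(secondary_score, th, direction, primary_threshold)
    m <- confusion_metrics(classify_sieve(data, rule), y)
    dplyr::mutate(m, threshold = th, positives = m$tp + m$fp)
  })
  feasible <- grid$sensitivity >= sens_min
  pick <- if (any(feasible)) {
    g <- grid[feasible, ]
    g <- g[order(-g$specificity, g$positives, g$threshold), ]
    g[1, ]
  } else {
    g <- grid[order(-grid$sensitivity, -grid$specificity, grid$positives,
                    grid$threshold), ]
    g[1, ]
  }
  list(
    rule = sieve_rule(secondary_score, pick$threshold, direction,
                      primary_threshold),
    threshold = pick$threshold,
    feasible = any(feasible),
    metrics = dplyr::select(pick, -"threshold", -"positives")
  )
}

#' Optimize a probability threshold under a sensitivity floor
#'
#' For a probabilistic classifier with decision rule "positive iff predicted
#' probability >= tau", chooses tau from the sorted distinct training
#' probabilities (plus a 0 sentinel) to maximize specificity subject to
#' sensitivity >= `sens_min` on the training data. The 0 sentinel classifies
#' everyone positive, so the floor is always attainable when cases exist;
#' the fallback (maximize sensitivity, ties by specificity) matches the
#' secondary-threshold optimizer. Ties in specificity are broken towards the
#' larger tau (fewest positives).
#'
#' @param probabilities Fitted probabilities in \[0, 1\].
#' @param labels Aligned logical/0-1 case labels (both classes present).
#' @param sens_min Sensitivity floor (default 0.95).
#' @return A list with `tau`, `feasible`, and the achieved training
#'   `metrics`.
#' @export
#' @examples
#' optimize_probability_threshold(c(0.1, 0.2, 0.6, 0.9), c(0, 0, 1, 1))
optimize_probability_threshold <- function(probabilities, labels,
                                           sens_min = 0.95) {
  if (any(probabilities < 0) || any(probabilities > 1)) {
    abort("`probabilities` must lie in [0, 1].",
          class = "cogsieve_validation_error")
  }
  y <- as.logical(labels)
  if (length(unique(y)) < 2) {
    abort("Training labels must contain both classes.",
          class = "cogsieve_validation_error")
  }
  candidates <- sort(unique(c(0, probabilities)))
  grid <- purrr::map_dfr(candidates, function(tau) {
    m <- confusion_metrics(probabilities >= tau, y)
    dplyr::mutate(m, tau = tau, positives = m$tp + m$fp)
  })
  feasible <- grid$sensitivity >= sens_min
  pick <- if (any(feasible)) {
    g <- grid[feasible, ]
    g <- g[order(-g$specificity, g$positives, -g$tau), ]
    g[1, ]
  } else {
    g <- grid[order(-grid$sensitivity, -grid$specificity, grid$positives), ]
    g[1, ]
  }
  list(tau = pick$tau, feasible = any(feasible),
       metrics = dplyr::select(pick, -"tau", -"positives"))
}
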