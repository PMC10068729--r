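#' Welch's unequal-variance t test
#'
#' @param x,y Numeric samples, each with at least 2 observations and positive
#'   variance.
#' @return A tibble with `statistic`, `df` (Welch-Satterthwaite), and the
#'   two-sided `p_value`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Welch's t test needs at least 2 observations per sample.",
          class = "cogsieve_validation_error")
  }
  if (var(x) == 0 && var(y) == 0) {
    abort("Welch's t test undefined when both samples are constant.",
          class = "cogsieve_validation_error")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return A tibble with the sample odds ratio (`NA`, the undefined flag,
#'   when a zero margin makes it undefined) and the conditional exact
#'   two-sided `p_value`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(10, 10, 10, 10), 2))
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    abort("`table` must be a 2x2 matrix of nonnegative integer counts.",
          class = "cogsieve_validation_error")
  }
  or <- if (table[1, 2] == 0 || table[2, 1] == 0) NA_real_ else
    (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  tibble::tibble(odds_ratio = or, p_value = fisher.test(table)$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic for the first sample. The p-value is
#' exact (full enumeration) when both samples are small
#' (`min(n1, n2) <= 8`) and tie-free, and otherwise uses the normal
#' approximation with continuity and tie correction.
#'
#' @param x,y Nonempty numeric samples.
#' @return A tibble with `u` and the two-sided `p_value`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Mann-Whitney test needs nonempty samples.",
          class = "cogsieve_validation_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  tibble::tibble(u = unname(ht$statistic), p_value = ht$p.value)
}

#' Covariate-adjusted group effect for one measure
#'
#' Fits the measure against diagnostic group plus the demographic covariates
#' (age, sex, education level, as in the published Table-1 comparisons) and
#' returns the group contrast of controls relative to patients:
#' \describe{
#'   \item{`adjusted_linear`}{Gaussian linear model; estimate = adjusted mean
#'     difference (control - ndg).}
#'   \item{`adjusted_logistic`}{Logistic regression for binary measures;
#'     estimate = odds ratio, SE by the delta method.}
#'   \item{`adjusted_scaled_binomial`}{For bounded scores with a known
#'     maximum, a binomial GLM with logit link treating the score as
#'     successes out of `maximum`; estimate = average marginal mean
#'     difference on the response (score) scale, SE by the delta method.}
#' }
#'
#' @param cohort Cohort tibble restricted internally to `groups`.
#' @param measure Column name of the dependent measure.
#' @param family One of `adjusted_linear`, `adjusted_logistic`,
#'   `adjusted_scaled_binomial`.
#' @param covariates Adjustment covariates (default age, sex, education
#'   level). May be empty, in which case `adjusted_linear` reduces exactly to
#'   the two-group least-squares mean difference.
#' @param maximum Score maximum, required for `adjusted_scaled_binomial`.
#' @param groups The two groups contrasted (default control vs ndg; the
#'   estimate is first minus second).
#' @return A one-row tibble `measure, family, estimate, se, p_value`.
#' @export
adjusted_group_effect <- function(cohort, measure,
                                  family = c("adjusted_linear",
                                             "adjusted_logistic",
                                             "adjusted_scaled_binomial"),
                                  covariates = c("age", "sex",
                                                 "education_level"),
                                  maximum = NULL,
                                  groups = c("control", "ndg")) {
  family <- match.arg(family)
  missing_cols <- setdiff(c(measure, covariates, "group"), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  data <- dplyr::filter(cohort, .data$group %in% groups)
  # reference level = second group, so the reported coefficient is
  # groups[1] relative to groups[2]
  data$group <- factor(data$group, levels = rev(groups))
  if (family == "adjusted_scaled_binomial") {
    if (is.null(maximum) || is.na(maximum)) {
      abort("`maximum` is required for the scaled-binomial family.",
            class = "cogsieve_validation_error")
    }
    if (any(data[[measure]] < 0) || any(data[[measure]] > maximum)) {
      abort(sprintf("`%s` must lie in [0, %s] for the scaled-binomial family.",
                    measure, maximum), class = "cogsieve_validation_error")
    }
    if (var(data[[measure]]) == 0) {
      abort(sprintf("`%s` is degenerate (constant); scaled-binomial fit undefined.",
                    measure), class = "cogsieve_validation_error")
    }
  }
  rhs <- paste(c("group", covariates), collapse = " + ")
  fit <- switch(
    family,
    adjusted_linear = lm(as.formula(paste(measure, "~", rhs)), data = data),
    adjusted_logistic = glm(
      as.formula(paste(sprintf("as.numeric(%s)", measure), "~", rhs)),
      family = binomial(), data = data),
    adjusted_scaled_binomial = glm(
      as.formula(paste(sprintf("cbind(%s, %d - %s)", measure,
                               as.integer(maximum), measure), "~", rhs)),
      family = binomial(), data = data)
  )
  cf <- coef(fit)
  if (any(is.na(cf))) {
    abort("Collinear design: some coefficients are not estimable.",
          class = "cogsieve_validation_error")
  }
  term <- paste0("group", groups[1])
  sm <- summary(fit)$coefficients
  b <- sm[term, 1]; se_b <- sm[term, 2]; p <- sm[term, 4]
  out <- switch(
    family,
    adjusted_linear = list(estimate = b, se = se_b),
    adjusted_logistic = list(estimate = exp(b), se = exp(b) * se_b),
    adjusted_scaled_binomial = scaled_binomial_md(fit, data, term, maximum,
                                                  groups)
  )
  tibble::tibble(measure = measure, family = family,
                 estimate = out$estimate, se = out$se, p_value = p)
}

# Average marginal mean difference (on the score scale) between the two
# groups for a scaled-binomial GLM, with a delta-method SE over the full
# coefficient vector.
scaled_binomial_md <- function(fit, data, term, maximum, groups) {
  ame <- function(beta) {
    f <- fit
    f$coefficients <- beta
    d1 <- d0 <- data
    d1$group <- factor(groups[1], levels = levels(data$group))
    d0$group <- factor(groups[2], levels = levels(data$group))
    maximum * mean(predict(f, newdata = d1, type = "response") -
                     predict(f, newdata = d0, type = "response"))
  }
  beta <- coef(fit)
  est <- ame(beta)
  eps <- 1e-6
  grad <- vapply(seq_along(beta), function(j) {
    bj <- beta
    bj[j] <- bj[j] + eps
    (ame(bj) - est) / eps
  }, numeric(1))
  list(estimate = est, se = sqrt(drop(t(grad) %*% vcov(fit) %*% grad)))
}

#' Default measure manifest for the group-comparison table
#'
#' Mirrors the published case-control table for the digital battery block:
#' bounded scores (the 5-WT totals) use the scaled-binomial family with their
#' instrument maxima, the remaining quantitative scores the Gaussian family,
#' and the comorbidity indicators logistic regression.
#'
#' @return A tibble with columns `measure`, `family`, `maximum`.
#' @export
default_manifest <- function() {
  tibble::tibble(
    measure = c("macnair", "gds", "nct_good", "nct_wrong", "nct_total",
                "fwt_total", "fwt_weighted", "tmt_a_s", "tmt_b_s",
                "tmt_delta_s", "mmse", "fab", "fcsrt_free", "fcsrt_total",
                "sus_score", "hypertension", "diabetes", "cardiovascular",
                "depression"),
    family = c(rep("adjusted_linear", 5), rep("adjusted_scaled_binomial", 2),
               rep("adjusted_linear", 3), rep("adjusted_scaled_binomial", 4),
               "adjusted_linear", rep("adjusted_logistic", 4)),
    maximum = c(rep(NA, 5), 10, 20, rep(NA, 3), 30, 18, 48, 48, NA,
                rep(NA, 4))
  )
}

#' Covariate-adjusted group-comparison table
#'
#' Runs [adjusted_group_effect()] for every measure in the manifest and
#' applies Benjamini-Hochberg correction across the table (one multiplicity
#' family per table block).
#'
#' @param cohort Cohort tibble.
#' @param manifest Tibble with columns `measure`, `family`, and `maximum`
#'   (see [default_manifest()]).
#' @param covariates,groups Passed to [adjusted_group_effect()].
#' @return A tibble `measure, family, estimate, se, p_raw, p_bh`.
#' @export
group_comparison_table <- function(cohort, manifest = default_manifest(),
                                   covariates = c("age", "sex",
                                                  "education_level"),
                                   groups = c("control", "ndg")) {
  res <- purrr::pmap_dfr(manifest, function(measure, family, maximum) {
    r <- adjusted_group_effect(cohort, measure, family,
                               covariates = covariates,
                               maximum = maximum, groups = groups)
    dplyr::rename(r, p_raw = "p_value")
  })
  res$p_bh <- bh_adjust(res$p_raw)
  res
}
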