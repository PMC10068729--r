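#' Stratified k-fold assignment
#'
#' Partitions `n` subjects into `k` folds whose sizes differ by at most one,
#' optionally stratified (each stratum is split as evenly as the fold sizes
#' allow, and the per-stratum remainders are placed on the currently smallest
#' folds so the overall balance is preserved). Reproducible for a fixed seed.
#'
#' With the study's 129 diagnostic participants and k = 5 this yields fold
#' sizes 26/26/26/26/25, i.e. training sets of 103-104 subjects.
#'
#' @param n Number of subjects (`n >= k`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @param strata Optional vector of stratum labels of length `n`.
#' @return An integer vector of fold ids in `1..k`.
#' @export
#' @examples
#' table(make_folds(129, 5, seed = 1))
make_folds <- function(n, k = 5L, seed = 1L, strata = NULL) {
  if (!is.numeric(n) || n < 1) abort("make_folds(): `n` must be positive.")
  if (!is.numeric(k) || k < 2) abort("make_folds(): `k` must be at least 2.")
  if (k > n) {
    abort(sprintf("make_folds(): cannot split n = %d subjects into k = %d folds.",
                  n, k), class = "cogsieve_validation_error")
  }
  if (is.null(strata)) strata <- rep(1L, n)
  if (length(strata) != n) {
    abort("make_folds(): `strata` must have length `n`.")
  }
  set.seed(seed)
  assignment <- integer(n)
  fold_sizes <- integer(k)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    base <- length(idx) %/% k
    r <- length(idx) %% k
    counts <- rep(base, k)
    if (r > 0) {
      # remainders go to the currently smallest folds, ties broken at random
      extra <- order(fold_sizes, sample.int(k))[seq_len(r)]
      counts[extra] <- counts[extra] + 1L
    }
    assignment[idx] <- rep.int(seq_len(k), counts)
    fold_sizes <- fold_sizes + counts
  }
  assignment
}

#' Cross-validated screening performance
#'
#' The study's evaluation harness: stratified fivefold cross-validation of
#' either the two-step clinician-guided sieve (secondary threshold optimized
#' per training fold under the sensitivity floor, see
#' [optimize_secondary_threshold()]) or the ridge-logistic classifier
#' (probability threshold optimized per training fold, see
#' [optimize_probability_threshold()]). Each fold's frozen rule is evaluated
#' on its held-out participants; metrics are aggregated as unweighted mean
#' and SD across folds.
#'
#' Only the two diagnostic classes enter the classifier: rows outside
#' `control`/`ndg` (e.g. post-COVID participants) are dropped before
#' splitting, and the positive label is membership of the neurodegenerative
#' group.
#'
#' @param cohort A cohort tibble with a `group` column.
#' @param method `"sieve"` or `"logistic"`.
#' @param secondary_score Secondary score for the sieve (default
#'   `"nct_good"`).
#' @param direction Secondary comparison direction; defaults to the score's
#'   clinical polarity ([default_direction()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param sens_min Sensitivity floor for the threshold optimization
#'   (default 0.95).
#' @param penalty Ridge weight for the logistic fit (default `1e-4`).
#' @return An object of class `cogsieve_cv`: `folds` (per-fold tibble with
#'   the chosen threshold, held-out test metrics and training metrics),
#'   `summary` (mean and SD of each test metric across folds), and the run
#'   metadata. `tidy()` returns the per-fold tibble, `glance()` the mean/SD
#'   row, and `autoplot()` draws the per-fold operating points.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(), seed = 7)
#' cv <- cross_validate(cohort, "sieve", seed = 7)
#' glance(cv)
cross_validate <- function(cohort, method = c("sieve", "logistic"),
                           secondary_score = "nct_good",
                           direction = default_direction(secondary_score),
                           k = 5L, seed = 1L, sens_min = 0.95,
                           penalty = 1e-4) {
  method <- match.arg(method)
  data <- dplyr::filter(cohort, .data$group %in% c("control", "ndg"))
  if (nrow(data) < k) {
    abort("make_folds(): fewer diagnostic participants than folds.",
          class = "cogsieve_validation_error")
  }
  y <- data$group == "ndg"
  if (length(unique(y)) < 2) {
    abort("Cohort must contain both diagnostic classes (control and ndg).",
          class = "cogsieve_validation_error")
  }
  folds <- make_folds(nrow(data), k, seed, strata = y)
  fold_rows <- purrr::map_dfr(seq_len(k), function(f) {
    train <- data[folds != f, ]
    test <- data[folds == f, ]
    y_train <- y[folds != f]
    y_test <- y[folds == f]
    if (length(unique(y_train)) < 2 || length(unique(y_test)) < 2) {
      abort(paste0("Fold ", f, " contains a single class; ",
                   "stratify the fold assignment."),
            class = "cogsieve_validation_error")
    }
    if (method == "sieve") {
      opt <- optimize_secondary_threshold(train, y_train, secondary_score,
                                          direction, sens_min)
      preds <- classify_sieve(test, opt$rule)
      threshold <- opt$threshold
    } else {
      fit <- fit_logistic(train, y_train, penalty = penalty)
      opt <- optimize_probability_threshold(predict(fit, train), y_train,
                                            sens_min)
      preds <- predict(fit, test) >= opt$tau
      threshold <- opt$tau
    }
    test_m <- confusion_metrics(preds, y_test)
    train_m <- dplyr::rename_with(opt$metrics, ~ paste0("train_", .x))
    dplyr::bind_cols(
      tibble::tibble(fold = f, n_train = nrow(train), n_test = nrow(test),
                     threshold = threshold, feasible = opt$feasible),
      test_m, train_m
    )
  })
  metrics <- c("sensitivity", "specificity", "ppv", "npv")
  summary <- purrr::map_dfr(metrics, function(m) {
    v <- fold_rows[[m]]
    tibble::tibble(metric = m, mean = mean(v, na.rm = TRUE),
                   sd = sd(v, na.rm = TRUE))
  })
  structure(list(folds = fold_rows, summary = summary, method = method,
                 secondary_score = if (method == "sieve") secondary_score
                 else NULL,
                 k = k, seed = seed, sens_min = sens_min),
            class = "cogsieve_cv")
}

#' @export
print.cogsieve_cv <- function(x, ...) {
  label <- if (x$method == "sieve") {
    sprintf("two-step sieve (secondary: %s)", x$secondary_score)
  } else "ridge-logistic classifier"
  cat(sprintf("%d-fold cross-validation of the %s\n", x$k, label))
  cat(sprintf("  sensitivity floor %.0f%%, seed %d\n",
              100 * x$sens_min, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %5.1f%% ± %4.1f%%\n", s$metric[i],
                100 * s$mean[i], 100 * s$sd[i]))
  }
  invisible(x)
}

#' @export
tidy.cogsieve_cv <- function(x, ...) x$folds

#' @export
glance.cogsieve_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(tibble::tibble(method = x$method, k = x$k,
                                  sens_min = x$sens_min), wide)
}

#' @export
autoplot.cogsieve_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[, c("fold", "sensitivity", "specificity", "ppv", "npv")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)), size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          linewidth = 0.3) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "held-out value", colour = "fold",
                  title = sprintf("%d-fold cross-validated operating points",
                                  object$k)) +
    ggplot2::theme_minimal()
}
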