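#' Pearson correlation with a t-based p-value
#'
#' Thin, validated wrapper around the sample Pearson coefficient; the
#' two-sided p-value comes from the t distribution with n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return A tibble with columns `n`, `r`, `p_value`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 3, 2))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
          class = "cogsieve_validation_error")
  }
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("Pearson correlation needs at least 3 complete pairs.",
          class = "cogsieve_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Pearson correlation undefined for a constant vector.",
          class = "cogsieve_validation_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(n = length(x), r = unname(ct$estimate),
                 p_value = ct$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard false-discovery-rate step-up: sort ascending, multiply the i-th
#' smallest p by m/i, enforce monotonicity by a cumulative minimum from the
#' largest rank, cap at 1, and return in the original order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return The adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "cogsieve_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Default digital/reference concordance pairs
#'
#' The three published pairs: verbal memory (5-WT total vs FCSRT total
#' recall), global intellectual efficiency (NCT good answers vs MMSE), and
#' executive function (TMT B - A vs FAB).
#'
#' @return A tibble with columns `digital` and `reference`.
#' @export
default_pairs <- function() {
  tibble::tibble(
    digital = c("fwt_total", "nct_good", "tmt_delta_s"),
    reference = c("fcsrt_total", "mmse", "fab")
  )
}

#' Digital versus reference concordance table
#'
#' Pearson correlation for each digital/reference score pair over the pooled
#' rows of the requested groups, complete cases per pair, with
#' Benjamini-Hochberg adjustment across the pairs of the table (the pairs
#' analysed together form one multiplicity family).
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param pairs A tibble with columns `digital` and `reference` naming cohort
#'   columns; defaults to [default_pairs()].
#' @param groups Character subset of `c("control", "ndg", "post_covid")`
#'   pooled for the analysis.
#' @return A tibble of class `cogsieve_concordance` with columns
#'   `pair, group_set, n, r, p_raw, p_bh`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(), seed = 1)
#' concordance_table(cohort)
concordance_table <- function(cohort, pairs = default_pairs(),
                              groups = c("control", "ndg")) {
  unknown <- setdiff(groups, GROUPS)
  if (length(unknown)) {
    abort(paste0("Unknown group(s): ", paste(unknown, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  cols <- c(pairs$digital, pairs$reference)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    abort(paste0("Unknown column(s): ", paste(missing, collapse = ", "), "."),
          class = "cogsieve_validation_error")
  }
  pooled <- dplyr::filter(cohort, .data$group %in% groups)
  res <- purrr::pmap_dfr(pairs, function(digital, reference) {
    pr <- pearson_r(pooled[[digital]], pooled[[reference]])
    tibble::tibble(pair = paste(digital, reference, sep = " ~ "),
                   group_set = paste(groups, collapse = "+"),
                   n = pr$n, r = pr$r, p_raw = pr$p_value)
  })
  res$p_bh <- bh_adjust(res$p_raw)
  class(res) <- c("cogsieve_concordance", class(res))
  res
}

#' @export
autoplot.cogsieve_concordance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pair, y = .data$r)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("r = %.2f", .data$r)),
                       vjust = ifelse(object$r >= 0, -0.4, 1.2)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Pearson r",
                  title = "Digital vs reference concordance",
                  subtitle = unique(object$group_set)) +
    ggplot2::theme_minimal()
}
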