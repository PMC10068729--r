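#' Noise SD for a linear counterpart with a target pooled correlation
#'
#' For a reference score built as `a + b * x + e`, `e ~ Normal(0, sigma^2)`,
#' returns the `sigma` for which the correlation between the reference score
#' and `x` equals `target_r` when `x` has pooled standard deviation
#' `pooled_sd_x`:
#' `sigma = |b| * sd_x * sqrt(1 / r^2 - 1)`.
#'
#' @param target_r Target Pearson correlation, in (-1, 1) and nonzero. Its
#'   sign must agree with the sign of `slope`.
#' @param pooled_sd_x Pooled standard deviation of the digital score `x`
#'   (positive).
#' @param slope The slope `b` of the linear construction (nonzero).
#' @return The noise standard deviation (a single positive number; 0 in the
#'   `|r| -> 1` limit).
#' @export
#' @examples
#' calibrate_counterpart_noise(0.5, 1, 1) # sqrt(3)
#' calibrate_counterpart_noise(-0.6, 2, -1) # 2 * sqrt(1 / 0.36 - 1)
calibrate_counterpart_noise <- function(target_r, pooled_sd_x, slope) {
  stopifnot_scalar_number(target_r, "target_r")
  stopifnot_scalar_number(pooled_sd_x, "pooled_sd_x")
  stopifnot_scalar_number(slope, "slope")
  if (abs(target_r) >= 1 || target_r == 0) {
    abort("`target_r` must be a nonzero correlation strictly inside (-1, 1).",
          class = "cogsieve_domain_error")
  }
  if (pooled_sd_x <= 0) abort("`pooled_sd_x` must be positive.")
  if (slope == 0) abort("`slope` must be nonzero.")
  if (sign(slope) != sign(target_r)) {
    abort("`slope` must have the same sign as `target_r`.",
          class = "cogsieve_domain_error")
  }
  abs(slope) * pooled_sd_x * sqrt(1 / target_r^2 - 1)
}

# Pooled (controls + NDG, weighted by group size) mean and SD implied by the
# configured class-conditional distributions, on the post-truncation scale.
pooled_digital_moments <- function(config, score) {
  w <- config$group_sizes[c("control", "ndg")]
  w <- if (sum(w) > 0) w / sum(w) else c(0.5, 0.5)
  if (score == "fwt_total") {
    stats <- lapply(c("control", "ndg"), function(g) {
      pmf <- config$fwt_pmf[[g]]
      m <- sum(0:10 * pmf)
      list(mean = m, sd = sqrt(sum((0:10 - m)^2 * pmf)))
    })
  } else {
    stats <- lapply(c("control", "ndg"), function(g) {
      sc <- config$scores[[score]]
      par <- solve_trunc_params(sc[[g]][1], sc[[g]][2], sc$lo, sc$hi)
      trunc_moments(par$mu, par$sigma, sc$lo, sc$hi)
    })
  }
  m <- w[1] * stats[[1]]$mean + w[2] * stats[[2]]$mean
  v <- w[1] * (stats[[1]]$sd^2 + (stats[[1]]$mean - m)^2) +
    w[2] * (stats[[2]]$sd^2 + (stats[[2]]$mean - m)^2)
  list(mean = m, sd = sqrt(v))
}

# Pooled controls+NDG mean/SD of a reference instrument from its configured
# group means and SDs.
pooled_reference_moments <- function(config, ref) {
  w <- config$group_sizes[c("control", "ndg")]
  w <- if (sum(w) > 0) w / sum(w) else c(0.5, 0.5)
  m_g <- config$reference_means[[ref]][c("control", "ndg")]
  s_g <- config$reference_sds[[ref]][c("control", "ndg")]
  m <- sum(w * m_g)
  list(mean = m, sd = sqrt(sum(w * (s_g^2 + (m_g - m)^2))))
}

# Linear construction (intercept, slope, noise SD) for each reference
# counterpart. The slope is the pooled-regression slope implied by the
# correlation target and the instrument's printed pooled SD
# (b = r * sd_ref / sd_x), and the intercept matches the printed pooled
# mean; the unclipped counterpart then reproduces the instrument's pooled
# mean and SD exactly, which keeps values inside the instrument bounds and
# the clipping distortion of the pooled correlation small.
counterpart_params <- function(config) {
  digital_of <- c(fcsrt_total = "fwt_total", mmse = "nct_good",
                  fab = "tmt_delta")
  out <- list()
  for (ref in names(digital_of)) {
    x <- digital_of[[ref]]
    pm <- pooled_digital_moments(config, x)
    rf <- pooled_reference_moments(config, ref)
    r <- config$correlation_targets[[ref]]
    b <- r * rf$sd / pm$sd
    a <- rf$mean - b * pm$mean
    sigma <- calibrate_counterpart_noise(r, pm$sd, b)
    out[[ref]] <- list(digital = x, intercept = a, slope = b, sigma = sigma)
  }
  # FCSRT free recall hangs off total recall; no correlation target is
  # configured for the pair, so the noise is set for a strong (r = 0.9)
  # free/total association with the same moment-matched construction.
  rt <- pooled_reference_moments(config, "fcsrt_total")
  rf <- pooled_reference_moments(config, "fcsrt_free")
  b <- 0.9 * rf$sd / rt$sd
  a <- rf$mean - b * rt$mean
  out$fcsrt_free <- list(
    digital = "fcsrt_total", intercept = a, slope = b,
    sigma = calibrate_counterpart_noise(0.9, rt$sd, b)
  )
  out
}

round_score <- function(x, rule, lo, hi) {
  x <- pmin(pmax(x, lo), hi)
  switch(rule,
         count = as.integer(round(x)),
         time = round(x, 1),
         sus = pmin(pmax(round(x / 2.5) * 2.5, lo), hi),
         x)
}

#' Generate a seeded synthetic validation cohort
#'
#' Draws one participant record per configured subject: demographics,
#' comorbidity indicators, digital battery scores (five-word test, number
#' coding test, trail making test, Mac Nair complaint scale, geriatric
#' depression scale, system usability scale) and reference neuropsychological
#' counterparts (FCSRT free/total recall, MMSE, FAB) built from their paired
#' digital score via a linear-plus-noise construction calibrated to the
#' configured pooled correlations. Continuous scores are truncated Gaussians
#' whose parent parameters are moment-matched so the truncated mean/SD equal
#' the configured values; times are rounded to 0.1 s and counts to integers.
#' TMT part B is generated as part A plus a positive increment, so B >= A
#' always.
#'
#' Each (group, variable) pair draws from its own deterministic child stream
#' of `seed`, so adding a variable does not perturb the others.
#'
#' @param config Generator configuration, see [default_config()].
#' @param seed Integer root seed.
#' @return A tibble with one row per participant and columns
#'   `id, group, age, sex, education_level, hypertension, diabetes,
#'   cardiovascular, depression, fwt_total, fwt_free_total, fwt_weighted,
#'   tmt_a_s, tmt_b_s, tmt_delta_s, nct_good, nct_wrong, nct_total, macnair,
#'   gds, mmse, fab, fcsrt_free, fcsrt_total, sus_score`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_config(), seed = 42)
#' dplyr::count(cohort, group)
generate_cohort <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  stopifnot_scalar_number(seed, "seed")
  cpar <- counterpart_params(config)
  prefix <- c(control = "C", ndg = "N", post_covid = "P")

  draw <- function(group, label, fun) {
    set.seed(child_seed(seed, group, label))
    fun()
  }

  groups <- GROUPS[config$group_sizes[GROUPS] > 0]
  rows <- lapply(groups, function(g) {
    n <- config$group_sizes[[g]]
    agec <- config$age[[g]]
    age <- draw(g, "age", function() {
      round(rtruncnorm(n, agec$mean, agec$sd, agec$lo, agec$hi), 2)
    })
    sex <- draw(g, "sex", function() {
      ifelse(runif(n) < config$female_frac[[g]], "female", "male")
    })
    edu <- draw(g, "education", function() {
      sample(1:3, n, replace = TRUE, prob = config$education_probs[[g]])
    })
    com <- lapply(COMORBIDITIES, function(cm) {
      draw(g, paste0("comorbidity_", cm), function() {
        runif(n) < config$comorbidity_prev[[g]][[cm]]
      })
    })
    names(com) <- COMORBIDITIES
    fwt_total <- draw(g, "fwt_total", function() {
      sample(0:10, n, replace = TRUE, prob = config$fwt_pmf[[g]])
    })
    p_free <- min(config$fwt_free_frac[[g]], 1)
    fwt_free <- draw(g, "fwt_free", function() rbinom(n, fwt_total, p_free))
    cont <- lapply(names(config$scores), function(s) {
      sc <- config$scores[[s]]
      par <- solve_trunc_params(sc[[g]][1], sc[[g]][2], sc$lo, sc$hi)
      draw(g, s, function() {
        round_score(rtruncnorm(n, par$mu, par$sigma, sc$lo, sc$hi),
                    sc$round, sc$lo, sc$hi)
      })
    })
    names(cont) <- names(config$scores)
    tmt_b <- round(cont$tmt_a + cont$tmt_delta, 1)
    digital <- list(fwt_total = fwt_total, nct_good = cont$nct_good,
                    tmt_delta = cont$tmt_delta)
    ref <- list()
    for (r in c("fcsrt_total", "mmse", "fab")) {
      cp <- cpar[[r]]
      x <- digital[[cp$digital]]
      b <- config$counterpart_bounds[[r]]
      ref[[r]] <- draw(g, paste0(r, "_noise"), function() {
        as_count(cp$intercept + cp$slope * x + rnorm(n, 0, cp$sigma),
                 b[1], b[2])
      })
    }
    cp <- cpar$fcsrt_free
    ref$fcsrt_free <- draw(g, "fcsrt_free_noise", function() {
      pmin(as_count(cp$intercept + cp$slope * ref$fcsrt_total +
                      rnorm(n, 0, cp$sigma), 0, 48),
           ref$fcsrt_total)
    })
    tibble::tibble(
      id = sprintf("%s%03d", prefix[[g]], seq_len(n)),
      group = g, age = age, sex = sex, education_level = as.integer(edu),
      hypertension = com$hypertension, diabetes = com$diabetes,
      cardiovascular = com$cardiovascular, depression = com$depression,
      fwt_total = as.integer(fwt_total),
      fwt_free_total = as.integer(fwt_free),
      fwt_weighted = as.integer(fwt_total + fwt_free),
      tmt_a_s = cont$tmt_a, tmt_b_s = tmt_b,
      tmt_delta_s = round(tmt_b - cont$tmt_a, 1),
      nct_good = cont$nct_good, nct_wrong = cont$nct_wrong,
      nct_total = as.integer(cont$nct_good + cont$nct_wrong),
      macnair = cont$macnair, gds = cont$gds,
      mmse = ref$mmse, fab = ref$fab,
      fcsrt_free = ref$fcsrt_free, fcsrt_total = ref$fcsrt_total,
      sus_score = cont$sus
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- empty_cohort()
  out
}

empty_cohort <- function() {
  tibble::tibble(
    id = character(), group = character(), age = numeric(),
    sex = character(), education_level = integer(),
    hypertension = logical(), diabetes = logical(),
    cardiovascular = logical(), depression = logical(),
    fwt_total = integer(), fwt_free_total = integer(),
    fwt_weighted = integer(), tmt_a_s = numeric(), tmt_b_s = numeric(),
    tmt_delta_s = numeric(), nct_good = integer(), nct_wrong = integer(),
    nct_total = integer(), macnair = integer(), gds = integer(),
    mmse = integer(), fab = integer(), fcsrt_free = integer(),
    fcsrt_total = integer(), sus_score = numeric()
  )
}

#' Read and write cohort CSV files
#'
#' The on-disk cohort format has one header row with the exact column set
#' produced by [generate_cohort()]; logical comorbidity indicators are stored
#' as 0/1 and missing values as empty fields.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  out <- dplyr::mutate(cohort,
                       dplyr::across(dplyr::all_of(COMORBIDITIES), as.integer))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, na = "", show_col_types = FALSE,
                            progress = FALSE)
  dplyr::mutate(cohort,
                dplyr::across(dplyr::all_of(COMORBIDITIES), as.logical),
                dplyr::across(dplyr::all_of(c(
                  "education_level", "fwt_total", "fwt_free_total",
                  "fwt_weighted", "nct_good", "nct_wrong", "nct_total",
                  "macnair", "gds", "mmse", "fab", "fcsrt_free",
                  "fcsrt_total")), as.integer))
}
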