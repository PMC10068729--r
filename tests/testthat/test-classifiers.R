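test_that("sieve classification applies the two steps as specified", {
  rule <- sieve_rule("nct_good", 15, "less_than")
  rec <- function(fwt, nct) tibble::tibble(fwt_total = fwt, nct_good = nct)
  # step 1: amnestic flag at 5-WT <= 9 regardless of the secondary score
  expect_true(classify_sieve(rec(8, 40), rule))
  expect_true(classify_sieve(rec(9, 40), rule))
  # step 2 among 5-WT = 10: strict comparison
  expect_false(classify_sieve(rec(10, 20), rule))
  expect_true(classify_sieve(rec(10, 14), rule))
  expect_false(classify_sieve(rec(10, 15), rule))
  # greater_than polarity for timed scores
  rule_t <- sieve_rule("tmt_b_s", 100, "greater_than")
  expect_true(classify_sieve(tibble::tibble(fwt_total = 10, tmt_b_s = 120),
                             rule_t))
  expect_false(classify_sieve(tibble::tibble(fwt_total = 10, tmt_b_s = 100),
                              rule_t))
  expect_error(classify_sieve(tibble::tibble(fwt_total = 10), rule),
               "nct_good")
  expect_error(
    classify_sieve(tibble::tibble(fwt_total = 10, nct_good = NA), rule),
    "impute")
})

test_that("confusion metrics compute the four operating characteristics", {
  perfect <- confusion_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  m <- confusion_metrics(
    rep(c(TRUE, FALSE, TRUE, FALSE), c(12, 1, 3, 9)),
    rep(c(TRUE, TRUE, FALSE, FALSE), c(12, 1, 3, 9)))
  expect_equal(m$sensitivity, 12 / 13)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$ppv, 0.8)
  expect_equal(m$npv, 0.9)
  # all-negative predictions leave PPV undefined
  none <- confusion_metrics(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_true(is.na(none$ppv))
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)),
               class = "cogsieve_validation_error")
})

test_that("secondary-threshold optimization reproduces the worked example", {
  # 20 cases: 18 flagged by step 1, 2 in the 5-WT = 10 subgroup
  # 20 controls: 4 false-positive at step 1, 16 in the subgroup
  data <- tibble::tibble(
    fwt_total = c(rep(5, 18), 10, 10, rep(9, 4), rep(10, 16)),
    nct_good = c(rep(30, 18), 10, 18, rep(30, 4), c(12, 20:34))
  )
  labels <- rep(c(TRUE, FALSE), each = 20)
  opt <- optimize_secondary_threshold(data, labels, "nct_good", "less_than",
                                      sens_min = 0.95)
  expect_equal(opt$threshold, 12)
  expect_true(opt$feasible)
  expect_equal(opt$metrics$sensitivity, 19 / 20)
  expect_equal(opt$metrics$specificity, 16 / 20)
})

test_that("step 1 alone meeting the floor yields the flag-nobody sentinel", {
  data <- tibble::tibble(
    fwt_total = c(rep(5, 20), rep(9, 2), rep(10, 18)),
    nct_good = c(rep(10, 20), rep(25, 20))
  )
  labels <- rep(c(TRUE, FALSE), each = 20)
  opt <- optimize_secondary_threshold(data, labels, "nct_good", "less_than",
                                      sens_min = 0.95)
  expect_equal(opt$threshold, -Inf)
  expect_equal(opt$metrics$sensitivity, 1)
  expect_equal(opt$metrics$specificity, 18 / 20)
  expect_error(
    optimize_secondary_threshold(data, rep(TRUE, 40), "nct_good"),
    "both classes")
})

test_that("secondary-threshold optimizer equals brute-force enumeration", {
  set.seed(77)
  for (i in 1:40) {
    data <- random_sieve_data(n = sample(15:40, 1),
                              n_values = sample(4:10, 1))
    labels <- runif(nrow(data)) < 0.45
    if (length(unique(labels)) < 2) next
    direction <- sample(c("less_than", "greater_than"), 1)
    sens_min <- sample(c(0.8, 0.95, 1), 1)
    opt <- optimize_secondary_threshold(data, labels, "nct_good", direction,
                                        sens_min)
    oracle <- sieve_oracle(data, labels, "nct_good", direction, sens_min)
    expect_equal(opt$metrics$sensitivity, oracle$sens)
    expect_equal(opt$metrics$specificity, oracle$spec)
    expect_equal(opt$metrics$tp + opt$metrics$fp, oracle$positives)
  }
})

test_that("whenever the floor is attainable the returned rule satisfies it", {
  set.seed(99)
  for (i in 1:30) {
    data <- random_sieve_data(n = 30)
    labels <- runif(30) < 0.5
    if (length(unique(labels)) < 2) next
    opt <- optimize_secondary_threshold(data, labels, "nct_good",
                                        "less_than", sens_min = 0.9)
    if (opt$feasible) expect_gte(opt$metrics$sensitivity, 0.9)
  }
})

test_that("sieve thresholds are monotone in sensitivity and specificity", {
  set.seed(55)
  data <- random_sieve_data(n = 60, n_values = 12)
  labels <- runif(60) < 0.5
  thresholds <- sort(unique(c(-Inf, data$nct_good, Inf)))
  ms <- purrr::map_dfr(thresholds, function(th) {
    confusion_metrics(
      classify_sieve(data, sieve_rule("nct_good", th, "less_than")), labels)
  })
  expect_true(all(diff(ms$sensitivity) >= 0))
  expect_true(all(diff(ms$specificity) <= 0))
  # step-1 dominance: the full rule only adds positives
  step1 <- confusion_metrics(
    classify_sieve(data, sieve_rule("nct_good", -Inf, "less_than")), labels)
  expect_true(all(ms$sensitivity >= step1$sensitivity))
  expect_true(all(ms$specificity <= step1$specificity))
})

test_that("probability-threshold optimization matches enumerated candidates", {
  opt <- optimize_probability_threshold(c(0.1, 0.2, 0.6, 0.9), c(0, 0, 1, 1),
                                        sens_min = 0.95)
  expect_equal(opt$tau, 0.6)
  expect_equal(opt$metrics$sensitivity, 1)
  expect_equal(opt$metrics$specificity, 1)
  # all-equal probabilities: everyone is classified positive
  opt_eq <- optimize_probability_threshold(rep(0.4, 6),
                                           c(1, 1, 1, 1, 0, 0), 0.95)
  expect_equal(opt_eq$tau, 0.4)
  expect_equal(opt_eq$metrics$sensitivity, 1)
  expect_equal(opt_eq$metrics$specificity, 0)
  set.seed(123)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    probs <- round(runif(n), 2)
    labels <- runif(n) < plogis(3 * (probs - 0.5))
    if (length(unique(labels)) < 2) next
    sens_min <- sample(c(0, 0.5, 0.95), 1)
    opt <- optimize_probability_threshold(probs, labels, sens_min)
    oracle <- prob_threshold_oracle(probs, labels, sens_min)
    expect_equal(opt$metrics$sensitivity, oracle$sens)
    expect_equal(opt$metrics$specificity, oracle$spec)
  }
  expect_error(optimize_probability_threshold(c(0.2, 1.3), c(0, 1)),
               class = "cogsieve_validation_error")
})

test_that("intercept-only logistic fit recovers the Bernoulli logit MLE", {
  fit <- fit_logistic(NULL, c(rep(1, 3), rep(0, 7)), penalty = 0)
  expect_equal(unname(coef(fit)), log(3 / 7), tolerance = 1e-8)
  expect_error(fit_logistic(matrix(rnorm(10)), rep(1, 10)), "both classes")
})

test_that("unpenalized logistic fit agrees with glm", {
  set.seed(42)
  n <- 300
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- runif(n) < plogis(-0.5 + x[, 1] - 0.8 * x[, 2])
  fit <- fit_logistic(x, y, penalty = 0)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(predict(fit, x)),
               unname(predict(ref, type = "response")), tolerance = 1e-6)
})

test_that("ridge penalty keeps separated and collinear fits finite", {
  x <- cbind(v = c(-2, -1.5, -1, 1, 1.5, 2))
  y <- c(0, 0, 0, 1, 1, 1) # perfectly separated
  fit <- fit_logistic(x, y, penalty = 0.01)
  expect_true(all(is.finite(coef(fit))))
  expect_equal(unname(predict(fit, x) >= 0.5), as.logical(y))
  # exactly collinear features (total = a + b) are tolerated
  xc <- cbind(a = rnorm(50), b = rnorm(50))
  xc <- cbind(xc, total = xc[, 1] + xc[, 2])
  yc <- runif(50) < plogis(xc[, 1])
  fitc <- fit_logistic(xc, yc, penalty = 1e-4)
  expect_true(all(is.finite(coef(fitc))))
})

test_that("logistic parameter recovery on simulated cohorts", {
  set.seed(7)
  n <- 5000
  beta <- c(-0.4, 0.9, -0.6)
  # 5 replicate simulations; a single 3-SE exceedance is within the nominal
  # ~1% per-coefficient rate, more than two is evidence of bias
  exceed <- 0
  for (rep in 1:5) {
    x <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    y <- runif(n) < plogis(beta[1] + x %*% beta[-1])
    fit <- fit_logistic(x, y, penalty = 1e-8)
    se <- sqrt(diag(vcov(glm(y ~ x, family = binomial()))))
    exceed <- exceed + sum(abs(coef(fit) - beta) >= 3 * se)
  }
  expect_lte(exceed, 2)
})

test_that("fold sizes reproduce the published 104/25 split arithmetic", {
  folds <- make_folds(129, 5, seed = 1)
  sizes <- as.integer(table(folds))
  expect_equal(sort(sizes), c(25L, 26L, 26L, 26L, 26L))
  expect_equal(sort(129 - sizes), c(103L, 103L, 103L, 103L, 104L))
  expect_equal(table(make_folds(10, 5, seed = 2)),
               table(rep(1:5, each = 2)))
  # exact stratification at balanced strata
  strata <- rep(c("a", "b"), each = 50)
  f <- make_folds(100, 5, seed = 3, strata = strata)
  expect_true(all(table(f, strata) == 10))
  expect_error(make_folds(4, 5), "make_folds")
  # determinism
  expect_identical(make_folds(129, 5, seed = 9, strata = rep(1:2, 65)[1:129]),
                   make_folds(129, 5, seed = 9, strata = rep(1:2, 65)[1:129]))
})

test_that("stratified folds keep both diagnostic classes near-balanced", {
  y <- rep(c(TRUE, FALSE), c(64, 65))
  f <- make_folds(129, 5, seed = 4, strata = y)
  tab <- table(f, y)
  expect_true(all(tab >= 12))
  expect_true(max(table(f)) - min(table(f)) <= 1)
})

test_that("cross-validation is deterministic and keeps folds disjoint", {
  cohort <- generate_cohort(default_config(), seed = 31)
  cv1 <- cross_validate(cohort, "sieve", seed = 5)
  cv2 <- cross_validate(cohort, "sieve", seed = 5)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_equal(sum(cv1$folds$n_test), 129)
  expect_equal(cv1$folds$n_train + cv1$folds$n_test, rep(129, 5))
  g <- glance(cv1)
  expect_true(all(c("sensitivity_mean", "specificity_sd") %in% names(g)))
  expect_true(all(g$sensitivity_mean >= 0 & g$sensitivity_mean <= 1))
})

test_that("a separable cohort cross-validates perfectly with the sieve", {
  n <- 60
  cohort <- tibble::tibble(
    id = as.character(1:n),
    group = rep(c("ndg", "control"), each = n / 2),
    fwt_total = rep(c(5L, 10L), each = n / 2),
    nct_good = rep(c(10L, 35L), each = n / 2)
  )
  cv <- cross_validate(cohort, "sieve", seed = 2)
  expect_equal(cv$summary$mean[cv$summary$metric == "sensitivity"], 1)
  expect_equal(cv$summary$mean[cv$summary$metric == "specificity"], 1)
})

test_that("logistic cross-validation honours the training sensitivity floor", {
  cohort <- generate_cohort(default_config(), seed = 13)
  cv <- cross_validate(cohort, "logistic", seed = 13)
  feasible <- cv$folds$feasible
  expect_true(any(feasible))
  expect_true(all(cv$folds$train_sensitivity[feasible] >= 0.95))
  # thresholds vary only through training data: refit is identical
  cv2 <- cross_validate(cohort, "logistic", seed = 13)
  expect_identical(cv$folds$threshold, cv2$folds$threshold)
})
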