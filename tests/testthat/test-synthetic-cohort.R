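test_that("counterpart noise calibration matches its closed form", {
  expect_equal(calibrate_counterpart_noise(0.5, 1, 1), sqrt(3))
  expect_equal(calibrate_counterpart_noise(-0.60, 2, -1),
               2 * sqrt(1 / 0.36 - 1))
  # noiseless limit
  expect_lt(calibrate_counterpart_noise(0.999999, 1, 1), 1e-2)
  expect_error(calibrate_counterpart_noise(0, 1, 1),
               class = "cogsieve_domain_error")
  expect_error(calibrate_counterpart_noise(1, 1, 1),
               class = "cogsieve_domain_error")
  expect_error(calibrate_counterpart_noise(0.5, 1, -1),
               class = "cogsieve_domain_error")
})

test_that("calibrated noise reproduces the target correlation in simulation", {
  set.seed(202)
  n <- 2e5
  x <- rnorm(n, 0, 2)
  sigma <- calibrate_counterpart_noise(-0.60, 2, -1)
  y <- 5 - x + rnorm(n, 0, sigma)
  expect_equal(cor(x, y), -0.60, tolerance = 0.01)
})

test_that("default configuration is valid and calibrated to the operating point", {
  cfg <- default_config()
  expect_silent(validate_config(cfg))
  for (g in c("control", "ndg", "post_covid")) {
    expect_equal(sum(cfg$fwt_pmf[[g]]), 1, tolerance = 1e-12)
  }
  # cumulative mass at <= 9 equals the published step-1 operating point
  expect_equal(sum(cfg$fwt_pmf$ndg[1:10]), 0.923, tolerance = 1e-12)
  expect_equal(sum(cfg$fwt_pmf$control[1:10]), 0.193, tolerance = 1e-12)
  expect_equal(unname(cfg$group_sizes), c(65L, 64L, 20L))
})

test_that("config validation names the offending field", {
  cfg <- default_config()
  cfg$fwt_pmf$ndg[1] <- cfg$fwt_pmf$ndg[1] + 0.01
  expect_error(validate_config(cfg), "fwt_pmf\\$ndg")
  cfg <- default_config()
  cfg$group_sizes["ndg"] <- -1L
  expect_error(validate_config(cfg), "group_sizes")
  cfg <- default_config()
  cfg$scores$nct_good$control[2] <- -2
  expect_error(validate_config(cfg), "nct_good")
})

test_that("generated cohorts have the configured sizes and record invariants", {
  cohort <- generate_cohort(default_config(), seed = 42)
  expect_equal(nrow(cohort), 149)
  counts <- dplyr::count(cohort, group)
  expect_equal(counts$n[match(c("control", "ndg", "post_covid"),
                              counts$group)], c(65L, 64L, 20L))
  expect_true(all(cohort$nct_total == cohort$nct_good + cohort$nct_wrong))
  expect_true(all(cohort$fwt_weighted ==
                    cohort$fwt_total + cohort$fwt_free_total))
  expect_true(all(cohort$fwt_free_total <= cohort$fwt_total))
  expect_true(all(cohort$fwt_total >= 0 & cohort$fwt_total <= 10))
  expect_true(all(cohort$tmt_b_s >= cohort$tmt_a_s))
  expect_true(all(cohort$tmt_a_s > 0))
  expect_true(all(cohort$mmse >= 0 & cohort$mmse <= 30))
  expect_true(all(cohort$fab >= 0 & cohort$fab <= 18))
  expect_true(all(cohort$fcsrt_total >= 0 & cohort$fcsrt_total <= 48))
  expect_true(all(cohort$fcsrt_free <= cohort$fcsrt_total))
  expect_true(all(cohort$gds >= 0 & cohort$gds <= 15))
  expect_true(all(cohort$sus_score >= 0 & cohort$sus_score <= 100))
  expect_true(all(cohort$sus_score %% 2.5 == 0))
})

test_that("cohort generation is deterministic and seed-sensitive", {
  cfg <- default_config()
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a, c))
})

test_that("all-zero group sizes yield an empty cohort without error", {
  cfg <- default_config()
  cfg$group_sizes[] <- 0L
  cohort <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(cohort), 0)
  expect_true(all(c("id", "group", "fwt_total", "sus_score") %in%
                    names(cohort)))
})

test_that("large-sample 5-WT frequencies recover the configured pmf", {
  cfg <- default_config()
  cfg$group_sizes <- c(control = 10000L, ndg = 10000L, post_covid = 0L)
  cohort <- generate_cohort(cfg, seed = 3)
  ndg <- cohort$fwt_total[cohort$group == "ndg"]
  p_hat <- mean(ndg <= 9)
  p_cfg <- sum(cfg$fwt_pmf$ndg[1:10])
  se <- sqrt(p_cfg * (1 - p_cfg) / 10000)
  expect_lt(abs(p_hat - p_cfg), 3 * se)
  ctl <- cohort$fwt_total[cohort$group == "control"]
  q_hat <- mean(ctl <= 9)
  q_cfg <- sum(cfg$fwt_pmf$control[1:10])
  expect_lt(abs(q_hat - q_cfg), 3 * sqrt(q_cfg * (1 - q_cfg) / 10000))
})

test_that("large-sample score means match the configured group means", {
  cfg <- default_config()
  cfg$group_sizes <- c(control = 10000L, ndg = 10000L, post_covid = 0L)
  cohort <- generate_cohort(cfg, seed = 5)
  for (g in c("control", "ndg")) {
    rows <- cohort[cohort$group == g, ]
    for (s in c("nct_good", "tmt_delta", "macnair", "gds")) {
      col <- if (s == "tmt_delta") "tmt_delta_s" else s
      target <- cfg$scores[[s]][[g]][1]
      sd_t <- cfg$scores[[s]][[g]][2]
      expect_lt(abs(mean(rows[[col]]) - target), 4 * sd_t / sqrt(10000),
                label = paste(g, s, "mean"))
    }
  }
})

test_that("cohort CSV round-trips through the documented on-disk format", {
  cohort <- generate_cohort(default_config(), seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  header <- readLines(path, n = 1)
  expect_equal(header, paste(
    "id,group,age,sex,education_level,hypertension,diabetes,cardiovascular",
    "depression,fwt_total,fwt_free_total,fwt_weighted,tmt_a_s,tmt_b_s",
    "tmt_delta_s,nct_good,nct_wrong,nct_total,macnair,gds,mmse,fab",
    "fcsrt_free,fcsrt_total,sus_score", sep = ","))
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(cohort))
  # identical config + seed => byte-identical file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(default_config(), seed = 9), path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("generator configuration round-trips through YAML", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$group_sizes, cfg$group_sizes)
  expect_equal(back$fwt_pmf$ndg, cfg$fwt_pmf$ndg, tolerance = 1e-12)
  expect_identical(generate_cohort(back, 4)$fwt_total,
                   generate_cohort(cfg, 4)$fwt_total)
})
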