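test_that("default configuration encodes the registry marginals and coefficients", {
  cfg <- cohort_config()
  expect_equal(cfg$n, 3184L)
  # count-derived probabilities agree with the published rounded percentages
  printed <- list(
    age_group = c(18.5, 21.0, 60.5), surgery = c(37.3, 62.7),
    tumor_size = c(14.7, 31.7, 53.6), nodes = c(9.9, 46.5, 43.6),
    stage = c(33.1, 20.8, 46.1), grade = c(35.0, 12.3, 52.8),
    lvi = c(57.1, 42.9), er = c(71.5, 28.5), pr = c(66.8, 33.2))
  for (v in names(printed)) {
    p <- cfg$covariate_probs[[v]]
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(100 * p), printed[[v]], tolerance = 0.06)
  }
  expect_equal(unname(round(cfg$covariate_probs$age_group[c("<40", "40-60", ">60")], 3)),
               c(0.210, 0.605, 0.185))
  expect_equal(unname(cfg$beta["lvipos"]), -1.139)
  expect_equal(unname(cfg$beta["tumor_sizeT1"]), 1.325)
})

test_that("the intercept is calibrated to the target mean cure fraction", {
  cfg <- cohort_config()
  expect_equal(mean_cure_fraction(cfg), 0.46, tolerance = 1e-9)
  cfg70 <- cohort_config(target_cure = 0.7)
  expect_equal(mean_cure_fraction(cfg70), 0.7, tolerance = 1e-9)
  expect_gt(cfg70$intercept, cfg$intercept)
})

test_that("generated cohorts match their configured cure fraction", {
  # null coefficients: cure is Bernoulli(0.46) exactly
  cfg <- cohort_config(n = 3184, beta = c(lvipos = 0), target_cure = 0.46)
  co <- generate_cohort(cfg, seed = 21)
  cured <- attr(co, "truth")$cured
  sd2 <- 2 * sqrt(0.46 * 0.54 / 3184)
  expect_lt(abs(mean(cured) - 0.46), sd2)
  # near-certain cure: nobody dies
  cfg_all <- cohort_config(n = 300, intercept = 30)
  co_all <- generate_cohort(cfg_all, seed = 1)
  expect_equal(sum(co_all$event), 0L)
})

test_that("the default cohort reproduces the registry censoring and marginals", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 1)
  expect_equal(nrow(co), 3184L)
  # censoring within 5 percentage points of 83%
  expect_lt(abs(100 * mean(co$event == 0) - 83), 5)
  # each covariate level frequency within 2 binomial sds of its target
  for (v in names(cfg$covariate_probs)) {
    p <- cfg$covariate_probs[[v]]
    obs <- as.numeric(table(co[[v]])[names(p)]) / nrow(co)
    expect_true(all(abs(obs - p) <= 2 * sqrt(p * (1 - p) / nrow(co)) + 1e-12),
                info = v)
  }
})

test_that("latent truth is internally consistent with the observed cohort", {
  co <- generate_cohort(cohort_config(n = 500), seed = 9)
  tr <- attr(co, "truth")
  expect_identical(tr$cured, is.infinite(tr$event_time))
  expect_equal(co$time, pmin(tr$event_time, tr$censor_time))
  expect_true(all(co$event[tr$cured] == 0))
  expect_identical(co$event, as.integer(tr$event_time <= tr$censor_time))
  expect_true(all(tr$theta > 0 & tr$theta < 1))
  # reproducibility
  co2 <- generate_cohort(cohort_config(n = 500), seed = 9)
  expect_identical(co, co2)
})

test_that("the Kaplan-Meier plateau sits at the configured cure fraction", {
  cfg <- cohort_config(n = 5000)
  co <- generate_cohort(cfg, seed = 1)
  km <- km_fit(co$time, co$event)
  q95 <- unname(quantile(co$time, 0.95))
  expect_lt(abs(survival_at(km, q95) - mean_cure_fraction(cfg)), 0.03)
})

test_that("raising the baseline cure odds lowers the event proportion", {
  cfg <- cohort_config(n = 2000)
  rates <- vapply(cfg$intercept + c(-2, -1, 0, 1, 2), function(b0) {
    co <- generate_cohort(cohort_config(n = 2000, intercept = b0), seed = 4)
    mean(co$event)
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n = 0), "n")
  expect_error(cohort_config(covariate_probs = list(lvi = c(0.7, 0.2))),
               "sum to 1")
  expect_error(cohort_config(covariate_probs = list(lvi = c(0.5))),
               "levels")
  expect_error(cohort_config(censor = list(min = -1, max = 23,
                                           shape1 = 1, shape2 = 1)),
               "censoring")
})
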