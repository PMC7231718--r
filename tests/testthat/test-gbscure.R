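test_that("a fitted model carries draws, acceptance rates and a sane summary", {
  fit <- small_fit()
  expect_s3_class(fit, "gbscure")
  expect_identical(colnames(fit$draws),
                   c("(Intercept)", "lvipos", "tumor_sizeT1", "tumor_sizeT2",
                     "alpha", "beta_scale", "nu"))
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(fit$draws[, c("alpha", "beta_scale", "nu")] > 0))
  expect_true(all(fit$accept > 0 & fit$accept < 1))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.gbscure")
  expect_true(all(sm$p25 <= sm$p50 & sm$p50 <= sm$p75))
  expect_equal(sm$exp_mean, exp(sm$mean))
  # significance flag is exactly "HPD excludes zero" for coefficient rows
  cf_rows <- setdiff(rownames(sm), c("alpha", "beta_scale", "nu"))
  recomputed <- vapply(cf_rows, function(p) {
    h <- hpd(fit$draws[, p])
    unname(h[1] > 0 | h[2] < 0)
  }, logical(1))
  expect_identical(unname(sm[cf_rows, "signif"]), unname(recomputed))
  expect_true(all(is.na(sm[c("alpha", "beta_scale", "nu"), "signif"])))
  expect_output(print(fit), "Promotion-time cure model")
  expect_output(print(sm), "HPD")
})

test_that("fits are bit-reproducible under a fixed seed", {
  co <- generate_cohort(cohort_config(n = 200), seed = 13)
  ctl <- gbscure_control(n_iter = 500, burn_in = 200, thin = 2, seed = 42)
  f1 <- gbscure(survival::Surv(time, event) ~ lvi, co, control = ctl)
  f2 <- gbscure(survival::Surv(time, event) ~ lvi, co, control = ctl)
  expect_identical(f1$draws, f2$draws)
  f3 <- gbscure(survival::Surv(time, event) ~ lvi, co,
                control = gbscure_control(n_iter = 500, burn_in = 200,
                                          thin = 2, seed = 43))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a synthetic cohort with a strong effect is recovered qualitatively", {
  co <- generate_cohort(cohort_config(n = 1500), seed = 31)
  fit <- gbscure(survival::Surv(time, event) ~ lvi + tumor_size, co,
                 control = gbscure_control(n_iter = 3000, burn_in = 1000,
                                           thin = 2, seed = 5))
  sm <- summary(fit)
  # lymphovascular invasion lowers the cure odds, clearly
  expect_lt(sm["lvipos", "mean"], -0.5)
  expect_true(sm["lvipos", "signif"])
  expect_gt(sm["tumor_sizeT1", "mean"], 0.3)
  # cure odds ratio below one for invasion
  expect_lt(sm["lvipos", "exp_mean"], 0.7)
})

test_that("methods expose coefficients, intervals, predictions and simulations", {
  fit <- small_fit()
  cf <- coef(fit)
  expect_false(any(c("alpha", "beta_scale", "nu") %in% names(cf)))
  ci <- confint(fit)
  expect_identical(colnames(ci), c("lower", "upper"))
  expect_true(all(ci[, 1] < ci[, 2]))
  nd <- data.frame(lvi = factor(c("neg", "pos"), c("neg", "pos")),
                   tumor_size = factor(c("T1", "T1"), c("T3+", "T1", "T2")))
  cure <- predict(fit, nd, type = "cure")
  expect_true(all(cure > 0 & cure < 1))
  expect_gt(cure[1], cure[2])      # invasion lowers the cure fraction
  tt <- c(0.05, 1, 5, 15, 40)
  sp <- predict(fit, nd, times = tt, type = "survival")
  expect_equal(dim(sp), c(5L, 2L))
  expect_true(all(diff(sp[, 1]) < 0))
  expect_gt(sp[1, 1], 0.97)
  expect_true(all(sp[5, ] >= cure - 0.05))
  ll <- logLik(fit)
  expect_true(is.finite(as.numeric(ll)))
  expect_equal(attr(ll, "df"), ncol(fit$draws))
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n, 2L))
  expect_true(all(sim > 0))
  expect_true(any(is.infinite(sim[, 1])))   # cured subjects
  expect_identical(sim, simulate(fit, nsim = 2, seed = 1))
})

test_that("doubling the prior scales barely moves the posterior", {
  co <- generate_cohort(cohort_config(n = 600), seed = 17)
  ctl <- gbscure_control(n_iter = 2500, burn_in = 1000, thin = 2, seed = 2)
  f1 <- gbscure(survival::Surv(time, event) ~ lvi, co, control = ctl)
  f2 <- gbscure(survival::Surv(time, event) ~ lvi, co,
                prior = gbscure_prior(beta_sd = 20, alpha_sd = 10,
                                      nu_sd = 10,
                                      scale_sd = 4 * median(co$time)),
                control = ctl)
  m1 <- colMeans(f1$draws)
  m2 <- colMeans(f2$draws)
  s1 <- apply(f1$draws, 2, sd)
  expect_true(all(abs(m1 - m2) < s1))
})

test_that("malformed model inputs fail loudly", {
  co <- generate_cohort(cohort_config(n = 100), seed = 1)
  expect_error(gbscure(time ~ lvi, co), "Surv")
  co$time[1] <- -1
  expect_error(gbscure(survival::Surv(time, event) ~ lvi, co), "> 0")
  expect_error(gbscure_control(n_iter = 100, burn_in = 200), "n_iter")
  expect_error(gbscure_prior(beta_sd = -1), "beta_sd")
})
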