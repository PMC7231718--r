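test_that("cure fraction follows the logit link and published odds ratios", {
  expect_equal(cure_fraction(c(1, 0, 0), rep(0, 3)), 0.5)
  # two subjects differing only in lymphovascular invasion
  x <- rbind(c(1, 0), c(1, 1))
  th <- cure_fraction(x, c(0.3, -1.139))
  odds <- th / (1 - th)
  or <- round(odds[2] / odds[1], 3)
  expect_equal(or, 0.320)
  # the reverse contrast as printed arithmetic: 1 / 0.320
  expect_equal(round(1 / or, 3), 3.125)
  expect_error(cure_fraction(c(1, 0), c(1, 2, 3)), "ncol")
})

test_that("population survival is the geometric pgf of the latent survival", {
  # S(beta) = 0.5, so Sp = 0.5 / (1 - 0.25) = 2/3
  expect_equal(pop_survival(2.5, 0.5, 0.9, 2.5), 2 / 3, tolerance = 1e-12)
  # theta = 1: everyone cured, survival identically one
  expect_equal(pop_survival(c(0.1, 5, 50), 1, 0.9, 2.5), rep(1, 3))
  # truncated-series oracle on random points
  set.seed(300)
  for (k in 1:50) {
    th <- runif(1, 0.05, 0.95)
    a <- runif(1, 0.3, 2); b <- runif(1, 0.5, 6); nu <- runif(1, 0.3, 1.5)
    t <- runif(1, 0.05, 20)
    S <- pgbs(t, a, b, nu, lower.tail = FALSE)
    expect_equal(pop_survival(t, th, a, b, nu), geom_series_sp(th, S),
                 tolerance = 1e-12)
  }
  # long-time limit is the cure fraction
  set.seed(301)
  for (k in 1:20) {
    th <- runif(1, 0.05, 0.95)
    a <- runif(1, 0.3, 2); b <- runif(1, 0.5, 6); nu <- runif(1, 0.3, 1.5)
    expect_equal(pop_survival(1e9, th, a, b, nu), th, tolerance = 1e-9)
  }
})

test_that("population survival decreases from 1 toward the plateau", {
  set.seed(302)
  for (k in 1:10) {
    th <- runif(1, 0.1, 0.9)
    tt <- seq(0.01, 40, length.out = 400)
    Sp <- pop_survival(tt, th, runif(1, 0.3, 2), runif(1, 0.5, 6),
                       runif(1, 0.3, 1.5))
    expect_true(all(diff(Sp) <= 0))
    expect_true(all(Sp >= th))
    expect_lt(abs(Sp[1] - 1), 0.05)
  }
})

test_that("population density is minus the survival derivative", {
  th <- 0.4; a <- 0.9; b <- 2.5; nu <- 0.5
  tt <- c(0.3, 1, 2.5, 6, 12)
  h <- 1e-5
  num <- -(pop_survival(tt + h, th, a, b, nu) -
             pop_survival(tt - h, th, a, b, nu)) / (2 * h)
  expect_equal(pop_density(tt, th, a, b, nu), num, tolerance = 1e-6)
  expect_equal(pop_density(tt, 1, a, b, nu), rep(0, length(tt)))
  # total mass is the susceptible fraction 1 - theta
  mass <- integrate(pop_density, 0, Inf, theta = th, alpha = a, beta = b,
                    nu = nu, rel.tol = 1e-10)$value
  expect_equal(mass, 1 - th, tolerance = 1e-6)
})

test_that("log likelihood equals the sum of per-subject terms", {
  # a cured-certain censored subject contributes log(1) = 0
  x1 <- matrix(1, 1, 1)
  expect_lt(abs(cure_loglik(10, 0, x1, 40, 0.9, 2.5, 0.5)), 1e-12)
  # 5-subject toy dataset, term-by-term oracle
  time <- c(0.8, 2, 3.5, 5, 9)
  event <- c(1, 0, 1, 0, 0)
  x <- cbind(1, c(0, 1, 1, 0, 1))
  beta <- c(-0.5, 1.1)
  th <- cure_fraction(x, beta)
  terms <- ifelse(event == 1,
                  pop_density(time, th, 0.7, 3, 0.6, log = TRUE),
                  pop_survival(time, th, 0.7, 3, 0.6, log = TRUE))
  expect_equal(cure_loglik(time, event, x, beta, 0.7, 3, 0.6), sum(terms),
               tolerance = 1e-12)
  # fully censored data far beyond the event-time scale: likelihood
  # increases with the cure fraction
  tc <- rep(50, 20)
  xc <- matrix(1, 20, 1)
  lls <- vapply(seq(-2, 3, length.out = 12), function(b0)
    cure_loglik(tc, rep(0, 20), xc, b0, 0.9, 2.5, 0.5), numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("likelihood inputs are validated and support is guarded", {
  x <- matrix(1, 2, 1)
  expect_error(cure_loglik(c(1, -1), c(0, 0), x, 0, 1, 1, 0.5), "time")
  expect_error(cure_loglik(c(1, 2), c(0, 2), x, 0, 1, 1, 0.5), "event")
  expect_identical(cure_loglik(c(1, 2), c(0, 1), x, 0, -1, 1, 0.5), -Inf)
  expect_error(pop_survival(1, 0, 1, 1, 0.5), "theta")
  expect_error(pop_survival(1, 1.2, 1, 1, 0.5), "theta")
})
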